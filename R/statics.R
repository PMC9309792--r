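# Posture generation and inverse statics: chain kinematics about the
# intervertebral joints, load-case application, and the net joint moments
# that the muscles must balance.
#
# Sign conventions: flexion (anterior rotation) is positive in postures and
# corresponds to a negative rotation about the joint's lateral (+Z-ish)
# axis, so extension moments are positive about +Z.  Moments are reported
# in the joint frame: M_x about the anterior axis (frontal-plane/lateral
# bending), M_y axial, M_z about the lateral axis (sagittal-plane
# flexion/extension).  N*m throughout; attachment coordinates in mm are
# converted internally.

#' Construct a posture
#'
#' @param model a `spine_model`
#' @param flexion_deg named per-joint sagittal rotations (flexion positive),
#'   degrees; missing joints default to 0
#' @param lateral_deg named per-joint frontal rotations (left bending
#'   positive), degrees
#' @param sacral_tilt_deg rigid anterior pelvic/sacral rotation applied at
#'   the lumbosacral pivot, degrees
#' @return object of class `posture`
#' @export
posture <- function(model, flexion_deg = NULL, lateral_deg = NULL,
                    sacral_tilt_deg = 0) {
  jn <- names(model$joints)
  fl <- stats::setNames(numeric(length(jn)), jn)
  lb <- fl
  if (!is.null(flexion_deg)) fl[names(flexion_deg)] <- flexion_deg
  if (!is.null(lateral_deg)) lb[names(lateral_deg)] <- lateral_deg
  stopifnot(all(is.finite(fl)), all(is.finite(lb)),
            is.finite(sacral_tilt_deg))
  structure(list(flexion_deg = fl, lateral_deg = lb,
                 sacral_tilt_deg = sacral_tilt_deg),
            class = "posture")
}

#' Trunk flexion split into sacral rotation and per-level lumbar flexion
#'
#' Applied trunk flexion is 40% sacral rotation and 60% lumbar flexion;
#' the lumbar share is distributed 25.5% to L1/L2, 23.1% to L2/L3, 20.4%
#' to L3/L4, 18.5% to L4/L5 and 12.5% to L5/S1.
#'
#' @param model a `spine_model`
#' @param trunk_flexion_deg total trunk flexion, degrees (validated range
#'   0..45; values outside produce a warning)
#' @return a `posture`
#' @export
flexion_posture <- function(model, trunk_flexion_deg) {
  if (trunk_flexion_deg < 0 || trunk_flexion_deg > 45)
    warning("trunk flexion ", trunk_flexion_deg,
            " deg is outside the validated 0-45 deg range")
  shares <- c("L1/L2" = 0.255, "L2/L3" = 0.231, "L3/L4" = 0.204,
              "L4/L5" = 0.185, "L5/S1" = 0.125)
  lumbar <- 0.6 * trunk_flexion_deg
  posture(model,
          flexion_deg = shares * lumbar,
          sacral_tilt_deg = 0.4 * trunk_flexion_deg)
}

#' Sum two postures (e.g. neutral compensation plus imposed flexion)
#' @param a,b `posture` objects over the same joints
#' @return a `posture`
#' @export
posture_add <- function(a, b) {
  structure(list(flexion_deg = a$flexion_deg + b$flexion_deg,
                 lateral_deg = a$lateral_deg + b$lateral_deg,
                 sacral_tilt_deg = a$sacral_tilt_deg + b$sacral_tilt_deg),
            class = "posture")
}

#' Per-body rigid transforms realizing a posture
#'
#' Joint rotations are applied about each joint's own origin and axes and
#' propagate superiorly along the chain; the sacral tilt acts as an
#' additional rotation at the lumbosacral joint.
#'
#' @param model a `spine_model`
#' @param pose a `posture`
#' @return named list of 4x4 transforms per body
#' @export
pose_model <- function(model, pose) {
  tf <- list(sacrum = diag(4))
  for (jn in names(model$joints)) {
    j <- model$joints[[jn]]
    f <- pose$flexion_deg[[jn]]
    if (jn == "L5/S1") f <- f + pose$sacral_tilt_deg
    b <- pose$lateral_deg[[jn]]
    Rj <- rot_axis(j$R[, "lateral"], -f) %*% rot_axis(j$R[, "anterior"], b)
    tf[[j$child]] <- tf[[j$parent]] %*% rotation_about_point(Rj, j$origin)
  }
  tf$arm_left <- tf$thorax
  tf$arm_right <- tf$thorax
  tf
}

#' Define a static load case
#'
#' @param name label
#' @param trunk_flexion_deg imposed trunk flexion, degrees
#' @param hand_mass_kg mass held in the hands, kg
#' @param load_offset_mm anterior offset of the held mass from the
#'   reference point, mm
#' @param reference named reference point for the offset: "chest" or
#'   "sacrum"
#' @param arms_elevated move the arm-dummy centres of mass to shoulder
#'   height at an anterior offset
#' @return object of class `load_case`
#' @export
load_case <- function(name, trunk_flexion_deg = 0, hand_mass_kg = 0,
                      load_offset_mm = 0, reference = "chest",
                      arms_elevated = FALSE) {
  stopifnot(hand_mass_kg >= 0)
  structure(list(name = name, trunk_flexion_deg = trunk_flexion_deg,
                 hand_mass_kg = hand_mass_kg,
                 load_offset_mm = load_offset_mm, reference = reference,
                 arms_elevated = arms_elevated),
            class = "load_case")
}

#' Attach a load case's external loads to the model
#'
#' The held mass becomes a point load rigidly attached to the thorax at
#' the stated anterior offset from the reference point; elevated arms move
#' the arm-dummy centres of mass to shoulder height at a configurable
#' anterior offset.
#'
#' @param model a `spine_model`
#' @param case a `load_case`
#' @param arm_elevation_offset_mm anterior arm-COM offset when elevated
#' @return modified `spine_model`
#' @export
apply_load_case <- function(model, case,
                            arm_elevation_offset_mm = 250) {
  model$external <- list()
  if (case$hand_mass_kg > 0) {
    ref <- switch(case$reference,
                  chest = model$points$chest$point,
                  sacrum = model$points$sacrum_sup$point,
                  stop("unknown load-case reference point: ",
                       case$reference))
    model$external <- list(list(
      name = "hand_load", body = "thorax",
      point = ref + c(case$load_offset_mm, 0, 0),
      force_n = c(0, -case$hand_mass_kg * GRAVITY_MS2, 0)))
  }
  if (isTRUE(case$arms_elevated)) {
    sc <- model$generic$geometry_scale
    for (sd in c("left", "right")) {
      bn <- paste0("arm_", sd)
      model$bodies[[bn]]$com <- model$bodies[[bn]]$shoulder +
        c(arm_elevation_offset_mm * sc, 0, 0)
    }
  }
  model
}

superstructure <- function(jn) {
  k <- which(JOINT_CHAIN$name == jn)
  bodies <- JOINT_CHAIN$child[k:nrow(JOINT_CHAIN)]
  if ("thorax" %in% bodies) bodies <- c(bodies, "arm_left", "arm_right")
  bodies
}

lig_crossing <- function(lig, super) {
  xor(lig$body_a %in% super, lig$body_b %in% super)
}

# ligament force vector acting on the superstructure and its application
# point, for a posed model
lig_force_on_super <- function(lig, tf, super) {
  pa <- apply_transform(tf[[lig$body_a]], lig$attach_a)
  pb <- apply_transform(tf[[lig$body_b]], lig$attach_b)
  l <- sqrt(sum((pa - pb)^2))
  F <- ligament_force(lig, l)
  if (lig$body_a %in% super) {
    list(point = pa, force = F * unitv(pb - pa))
  } else {
    list(point = pb, force = F * unitv(pa - pb))
  }
}

#' Net joint moments required to hold a posture
#'
#' For every actuated joint, the moment of gravity and external loads on
#' the superstructure about the (posed) joint origin, plus the moments of
#' ligament forces crossing the joint and the disc's restoring moment, are
#' summed; the returned value is the negated total, i.e. the moment the
#' muscles must generate, expressed in the joint frame (M_x frontal,
#' M_y axial, M_z sagittal).
#'
#' @param model a `spine_model` (with external loads already attached)
#' @param pose a `posture`
#' @param include_passive include ligament and disc contributions
#' @return matrix joints x (M_x, M_y, M_z), N*m
#' @export
net_joint_moments <- function(model, pose, include_passive = TRUE) {
  tf <- pose_model(model, pose)
  jn_all <- names(model$joints)
  out <- matrix(0, length(jn_all), 3,
                dimnames = list(jn_all, c("M_x", "M_y", "M_z")))
  for (jn in jn_all) {
    j <- model$joints[[jn]]
    super <- superstructure(jn)
    orig <- apply_transform(tf[[j$parent]], j$origin)
    M <- c(0, 0, 0)
    for (bn in super) {
      b <- model$bodies[[bn]]
      if (b$mass_kg <= 0) next
      com <- apply_transform(tf[[bn]], b$com)
      Fg <- c(0, -b$mass_kg * GRAVITY_MS2, 0)
      M <- M + cross3((com - orig) / 1000, Fg)
    }
    for (ex in model$external) {
      if (!(ex$body %in% super)) next
      p <- apply_transform(tf[[ex$body]], ex$point)
      M <- M + cross3((p - orig) / 1000, ex$force_n)
    }
    if (include_passive) {
      for (lig in model$ligaments) {
        if (!lig_crossing(lig, super)) next
        lf <- lig_force_on_super(lig, tf, super)
        M <- M + cross3((lf$point - orig) / 1000, lf$force)
      }
      # disc restoring moment from this joint's own rotation
      d <- model$discs[[jn]]
      rot <- c(frontal = unname(pose$lateral_deg[[jn]]),
               axial = 0,
               sagittal = -unname(pose$flexion_deg[[jn]]))  # extension +
      md <- disc_moment(d, rot)
      Rp <- tf[[j$parent]][1:3, 1:3] %*% j$R
      M <- M + as.numeric(Rp %*% c(md[["frontal"]], md[["axial"]],
                                   md[["sagittal"]]))
    }
    Rp <- tf[[j$parent]][1:3, 1:3] %*% j$R
    out[jn, ] <- as.numeric(t(Rp) %*% (-M))
  }
  out
}

#' Optimize the neutral standing posture
#'
#' Finds the sagittal joint angles (T12/L1 .. L5/S1, bounded to +/-10
#' degrees) minimizing the sum of squared sagittal net joint moments,
#' starting from the zero posture with fixed solver settings, so the result
#' is deterministic.
#'
#' @param model a `spine_model` (no external loads)
#' @param bounds_deg symmetric per-joint angle bound
#' @return a `posture`; attributes `objective` (N^2*m^2) and
#'   `max_abs_mz_nm`
#' @export
neutral_posture <- function(model, bounds_deg = 10) {
  jn <- names(model$joints)
  obj <- function(x) {
    p <- posture(model, flexion_deg = stats::setNames(x, jn))
    sum(net_joint_moments(model, p)[, "M_z"]^2)
  }
  fit <- stats::optim(rep(0, length(jn)), obj, method = "L-BFGS-B",
                      lower = -bounds_deg, upper = bounds_deg,
                      control = list(maxit = 200, factr = 1e7))
  p <- posture(model, flexion_deg = stats::setNames(fit$par, jn))
  attr(p, "objective") <- fit$value
  attr(p, "max_abs_mz_nm") <- max(abs(net_joint_moments(model, p)[, "M_z"]))
  attr(p, "convergence") <- fit$convergence
  if (fit$convergence != 0)
    warning("neutral-posture optimization did not converge (code ",
            fit$convergence, "); residual objective ", fit$value)
  p
}

#' Load-case battery analogous to the validation tasks
#'
#' Standing; standing holding 20 kg at 20 cm from the chest and at 55 cm
#' from the sacrum; 30 deg flexion; both arms elevated; and 10/20/30 deg
#' flexion without and with a 10 kg hand load.
#'
#' @return named list of `load_case` objects
#' @export
default_load_cases <- function() {
  lc <- list(
    load_case("standing"),
    load_case("standing_20kg_20cm_chest", hand_mass_kg = 20,
              load_offset_mm = 200, reference = "chest"),
    load_case("standing_20kg_55cm_sacrum", hand_mass_kg = 20,
              load_offset_mm = 550, reference = "sacrum"),
    load_case("flexion_30", trunk_flexion_deg = 30),
    load_case("arms_elevated", arms_elevated = TRUE),
    load_case("flexion_10", trunk_flexion_deg = 10),
    load_case("flexion_10_10kg", trunk_flexion_deg = 10,
              hand_mass_kg = 10, load_offset_mm = 300, reference = "chest"),
    load_case("flexion_20", trunk_flexion_deg = 20),
    load_case("flexion_20_10kg", trunk_flexion_deg = 20,
              hand_mass_kg = 10, load_offset_mm = 300, reference = "chest"),
    load_case("flexion_30_10kg", trunk_flexion_deg = 30,
              hand_mass_kg = 10, load_offset_mm = 300, reference = "chest"))
  stats::setNames(lc, vapply(lc, `[[`, character(1), "name"))
}

#' Read load cases from a YAML file
#'
#' Each entry: `name`, and optionally `trunk_flexion_deg`, `hand_mass_kg`,
#' `load_offset_mm`, `reference`, `arms_elevated`.
#'
#' @param path YAML file
#' @return named list of `load_case`
#' @export
read_load_cases <- function(path) {
  raw <- yaml::read_yaml(path)
  lc <- lapply(raw, function(x) do.call(load_case, x))
  stats::setNames(lc, vapply(lc, `[[`, character(1), "name"))
}
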