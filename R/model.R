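# Assembly of the static musculoskeletal model: rigid bodies (fused
# thorax/head/ribcage, lumbar vertebrae, sacrum-pelvis ground, arm
# dummies), actuated spherical joints T12/L1 .. L5/S1, ligament segments,
# lumped discs and the muscle actuator set.

BODY_CHAIN <- c(sacrum = 0L, L5 = 1L, L4 = 2L, L3 = 3L, L2 = 4L, L1 = 5L,
                thorax = 6L, arm_left = 6L, arm_right = 6L)

JOINT_CHAIN <- data.frame(
  name = c("L5/S1", "L4/L5", "L3/L4", "L2/L3", "L1/L2", "T12/L1"),
  parent = c("sacrum", "L5", "L4", "L3", "L2", "L1"),
  child = c("L5", "L4", "L3", "L2", "L1", "thorax"),
  stringsAsFactors = FALSE)

#' Assemble the patient-specific static spine model
#'
#' Combines extracted geometry, per-level tissue segments, bone masses,
#' scaled generic segments (head-neck, arms), ligament segments with
#' derived force-law parameters, disc elements and the muscle actuator set
#' into one serializable model.  The joint chain is
#' ground (sacrum/pelvis) -> L5 -> ... -> L1 -> thorax.
#'
#' @param geometry result of [extract_geometry()]
#' @param segments tissue segments from [assign_to_levels()]
#' @param instances instance `labeled_volume` (for bone masses)
#' @param stature_m body height used for generic-segment scaling, m
#' @param densities a [density_table()]
#' @param anthropometry see [default_anthropometry()]
#' @param ligament_params see [default_ligament_params()]
#' @param disc_params see [default_disc_params()]
#' @param muscle_table optional custom fascicle table
#' @param arm_hang_offset_mm arm-dummy centre of mass relative to the
#'   shoulder point when hanging (default 10 mm anterior, 280 mm inferior)
#' @return object of class `spine_model`
#' @export
assemble_model <- function(geometry, segments, instances,
                           stature_m = 1.74,
                           densities = density_table(),
                           anthropometry = default_anthropometry(),
                           ligament_params = default_ligament_params(),
                           disc_params = default_disc_params(),
                           muscle_table = NULL,
                           arm_hang_offset_mm = c(10, -280, 0)) {
  geoms <- geometry$geometries
  joints <- geometry$joints
  if (!all(JOINT_CHAIN$name %in% names(joints)))
    stop("missing joint(s): ",
         paste(setdiff(JOINT_CHAIN$name, names(joints)), collapse = ", "))

  seg_mass <- stats::setNames(segments$mass_kg, segments$level)
  seg_com <- as.matrix(segments[, c("com_x", "com_y", "com_z")])
  rownames(seg_com) <- segments$level
  bone_kg <- vapply(names(geoms), function(lv)
    bone_mass(instances, lv, densities), numeric(1))

  torso_mass <- sum(seg_mass) + sum(bone_kg)
  gen <- scale_generic_segments(stature_m, torso_mass, anthropometry)
  pts <- generic_points(geoms, gen$geometry_scale)

  wavg <- function(coms, masses) {
    keep <- masses > 0 & stats::complete.cases(coms)
    if (!any(keep)) return(c(NA_real_, NA_real_, NA_real_))
    colSums(coms[keep, , drop = FALSE] * masses[keep]) / sum(masses[keep])
  }
  bodies <- list()
  for (lv in paste0("L", 1:5)) {
    m <- c(bone_kg[[lv]], if (lv %in% names(seg_mass)) seg_mass[[lv]] else 0)
    coms <- rbind(geoms[[lv]]$centroid,
                  if (lv %in% rownames(seg_com)) seg_com[lv, ] else
                    c(NA, NA, NA))
    bodies[[lv]] <- list(name = lv, mass_kg = sum(m), com = wavg(coms, m),
                         levels = lv)
  }
  tl <- paste0("T", 1:12)
  th_m <- c(bone_kg[tl],
            seg_mass[intersect(tl, names(seg_mass))],
            head_neck = gen$head_neck_kg)
  th_c <- rbind(do.call(rbind, lapply(tl, function(lv) geoms[[lv]]$centroid)),
                seg_com[intersect(tl, rownames(seg_com)), , drop = FALSE],
                pts$head_neck_com$point)
  bodies$thorax <- list(name = "thorax", mass_kg = sum(th_m),
                        com = wavg(th_c, th_m), levels = tl)
  sac_m <- c(bone_kg[["sacrum"]],
             if ("sacrum" %in% names(seg_mass)) seg_mass[["sacrum"]] else 0)
  bodies$sacrum <- list(name = "sacrum", mass_kg = sum(sac_m),
                        com = geoms$sacrum$centroid, levels = "sacrum",
                        ground = TRUE)
  for (sd in c("left", "right")) {
    sh <- pts[[paste0("shoulder_", sd)]]$point
    bodies[[paste0("arm_", sd)]] <- list(
      name = paste0("arm_", sd), mass_kg = gen$arm_kg,
      com = sh + arm_hang_offset_mm * gen$geometry_scale,
      levels = character(0), shoulder = sh)
  }

  # ligament segments at each articulated joint
  sup_of <- stats::setNames(c("T12", paste0("L", 1:5)), JOINT_CHAIN$name)
  inf_of <- stats::setNames(c(paste0("L", 1:5), "sacrum"), JOINT_CHAIN$name)
  ligaments <- list()
  for (jn in JOINT_CHAIN$name) {
    slv <- sup_of[[jn]]; ilv <- inf_of[[jn]]
    for (nm in names(ligament_params)) {
      lp <- ligament_params[[nm]]
      a_name <- lp$attach_sup
      b_name <- if (ilv == "sacrum" && !is.null(lp$attach_inf_sacrum))
        lp$attach_inf_sacrum else lp$attach_inf
      pa <- geoms[[slv]]$landmarks[[a_name]]
      pb <- geoms[[ilv]]$landmarks[[b_name]]
      if (is.null(pa) || is.null(pb)) next
      lig <- derive_ligament_params(nm, jn, pa, pb, lp$n, lp$eps_pre,
                                    lp$eps_A, lp$eps_B, lp$F_A, lp$F_B)
      lig$body_a <- body_of_level(slv)
      lig$body_b <- body_of_level(ilv)
      ligaments[[paste(nm, jn)]] <- lig
    }
  }

  discs <- lapply(JOINT_CHAIN$name, function(jn)
    disc_element(jn,
                 unlist(disc_params$neutral_zone_deg),
                 unlist(disc_params$stiffness_nm_per_deg)))
  names(discs) <- JOINT_CHAIN$name

  muscles <- build_muscles(geoms, pts, muscle_table)

  jl <- lapply(JOINT_CHAIN$name, function(jn) {
    j <- joints[[jn]]
    list(name = jn, origin = j$origin, R = j$R,
         parent = JOINT_CHAIN$parent[JOINT_CHAIN$name == jn],
         child = JOINT_CHAIN$child[JOINT_CHAIN$name == jn])
  })
  names(jl) <- JOINT_CHAIN$name

  structure(list(
    bodies = bodies, joints = jl, ligaments = ligaments, discs = discs,
    muscles = muscles, points = pts,
    alignment = geometry$alignment,
    generic = gen, stature_m = stature_m,
    external = list(),
    provenance = list(
      densities = unclass(densities),
      anthropometry = anthropometry,
      n_muscle_actuators = nrow(muscles),
      n_muscle_groups = length(unique(muscles$group)))),
    class = "spine_model")
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model> ", length(x$bodies), " bodies, ",
      length(x$joints), " actuated joints, ", length(x$ligaments),
      " ligament segments, ", nrow(x$muscles), " muscle actuators (",
      length(unique(x$muscles$group)), " groups)\n", sep = "")
  cat("  total mass ", round(total_model_mass(x), 2), " kg\n", sep = "")
  invisible(x)
}

#' Total model mass (all bodies)
#' @param model a `spine_model`
#' @return kg
#' @export
total_model_mass <- function(model) {
  sum(vapply(model$bodies, `[[`, numeric(1), "mass_kg"))
}

#' Serialize a model to JSON
#' @param model a `spine_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
model_to_json <- function(model, path) {
  enc <- model
  enc$joints <- lapply(model$joints, function(j) {
    j$R <- as.vector(j$R); j
  })
  enc$ligaments <- lapply(model$ligaments, unclass)
  enc$discs <- lapply(model$discs, function(d) {
    # jsonlite drops names of atomic vectors; keep the per-axis names
    list(level = d$level,
         neutral_zone_deg = as.list(d$neutral_zone_deg),
         stiffness_nm_per_deg = as.list(d$stiffness_nm_per_deg))
  })
  enc$muscles <- as.data.frame(unclass(model$muscles))
  class(enc) <- NULL
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a model back from JSON
#' @param path JSON path written by [model_to_json()]
#' @return a `spine_model`
#' @export
model_from_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$joints <- lapply(m$joints, function(j) {
    j$R <- matrix(j$R, 3, 3, dimnames = list(NULL, c("anterior", "superior",
                                                     "lateral")))
    j
  })
  m$bodies <- lapply(m$bodies, function(b) { b$com <- as.numeric(b$com); b })
  m$ligaments <- lapply(m$ligaments, function(l) {
    l$attach_a <- as.numeric(l$attach_a)
    l$attach_b <- as.numeric(l$attach_b)
    class(l) <- "ligament_element"; l
  })
  m$discs <- lapply(m$discs, function(d) {
    d$neutral_zone_deg <- unlist(d$neutral_zone_deg)
    d$stiffness_nm_per_deg <- unlist(d$stiffness_nm_per_deg)
    class(d) <- "disc_element"; d
  })
  m$muscles <- as.data.frame(m$muscles)
  m$points <- lapply(m$points, function(p) {
    p$point <- as.numeric(p$point); p
  })
  class(m) <- "spine_model"
  m
}
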