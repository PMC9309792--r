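# Static optimization of muscle forces: minimize the sum of cubed muscle
# stresses sum_i (F_i / PCSA_i)^3 subject to frontal and sagittal
# moment-equilibrium equality constraints at every actuated joint and the
# bounds 0 <= F_i <= sigma_max * PCSA_i.  The cost is convex on the feasible
# box, so a deterministic augmented-Lagrangian descent (with optional fixed
# multi-start verification) reaches the global optimum.  Joint reactions are
# decomposed in the joint frame into compression, anterior-posterior shear
# and lateral shear.

#' Moment arm of a point-to-point fascicle about a joint
#'
#' `r x u` with `r` the vector from the joint origin to the
#' superstructure-side attachment (m) and `u` the unit line of action of
#' the pull at that attachment.
#'
#' @param attach_point attachment on the superstructure side, mm
#' @param other_point opposite attachment, mm
#' @param joint_origin joint origin, mm
#' @return 3-vector of moment per unit force, N*m/N (i.e. metres)
#' @export
moment_arm <- function(attach_point, other_point, joint_origin) {
  u <- unitv(other_point - attach_point)
  cross3((attach_point - joint_origin) / 1000, u)
}

#' Build the static optimization problem for a posed, loaded model
#'
#' Equality constraints cover the frontal (M_x) and sagittal (M_z) moment
#' components at the six actuated joints; axial moments are left
#' unconstrained.  Targets are the net joint moments (gravity, external,
#' ligament and disc contributions).
#'
#' @param model a `spine_model` with external loads attached
#' @param pose a `posture`
#' @param sigma_max_mpa maximal muscle stress bound, MPa
#' @return an `optimization_problem`
#' @export
build_problem <- function(model, pose, sigma_max_mpa = 0.6) {
  tf <- pose_model(model, pose)
  mus <- model$muscles
  n <- nrow(mus)
  jn_all <- names(model$joints)
  req <- net_joint_moments(model, pose)
  A <- matrix(0, 2 * length(jn_all), n)
  rn <- character(2 * length(jn_all))
  b <- numeric(2 * length(jn_all))
  po <- lapply(seq_len(n), function(i)
    apply_transform(tf[[mus$origin_body[i]]],
                    c(mus$ox[i], mus$oy[i], mus$oz[i])))
  pi_ <- lapply(seq_len(n), function(i)
    apply_transform(tf[[mus$insertion_body[i]]],
                    c(mus$ix[i], mus$iy[i], mus$iz[i])))
  for (k in seq_along(jn_all)) {
    jn <- jn_all[k]
    j <- model$joints[[jn]]
    super <- superstructure(jn)
    orig <- apply_transform(tf[[j$parent]], j$origin)
    Rp <- tf[[j$parent]][1:3, 1:3] %*% j$R
    for (i in seq_len(n)) {
      o_in <- mus$origin_body[i] %in% super
      i_in <- mus$insertion_body[i] %in% super
      if (o_in == i_in) next                       # not crossing this joint
      ma <- if (o_in) moment_arm(po[[i]], pi_[[i]], orig)
            else moment_arm(pi_[[i]], po[[i]], orig)
      mj <- as.numeric(t(Rp) %*% ma)               # joint-frame moment arm
      A[2 * k - 1, i] <- mj[1]                     # frontal (M_x)
      A[2 * k, i] <- mj[3]                         # sagittal (M_z)
    }
    rn[2 * k - 1] <- paste0(jn, ":M_x")
    rn[2 * k] <- paste0(jn, ":M_z")
    b[2 * k - 1] <- req[jn, "M_x"]
    b[2 * k] <- req[jn, "M_z"]
  }
  rownames(A) <- rn
  structure(list(moment_arms = A, target = stats::setNames(b, rn),
                 pcsa = mus$pcsa_cm2, sigma_max_mpa = sigma_max_mpa,
                 constraint_names = rn, muscles = mus),
            class = "optimization_problem")
}

#' Solve the static optimization problem
#'
#' Deterministic augmented-Lagrangian minimization of the cubed-stress cost
#' under the moment-equality constraints and force bounds
#' `0 <= F_i <= sigma_max * PCSA_i` (sigma_max in MPa = 100 N/cm^2).
#' If the equality constraints cannot be met within `tol`, an error of
#' class `spineload_infeasible` reports the worst joint.
#'
#' @param problem an `optimization_problem`
#' @param tol equality-constraint tolerance, N*m
#' @param n_starts deterministic multi-start count (fixed seed); the
#'   problem is convex, so extra starts are verification only
#' @param seed seed for the multi-start jitter
#' @return object of class `static_solution`: forces (N), cost, residuals
#' @export
solve_static <- function(problem, tol = 0.1, n_starts = 1, seed = 1L) {
  A <- problem$moment_arms
  b <- as.numeric(problem$target)
  P <- problem$pcsa
  ub <- problem$sigma_max_mpa * 100 * P            # N (1 MPa = 100 N/cm^2)
  n <- length(P)

  solve_from <- function(F0) {
    lam <- numeric(length(b))
    mu <- 1e3
    F <- pmin(pmax(F0, 0), ub)
    res_prev <- Inf
    for (outer in 1:40) {
      fn <- function(F) {
        c_ <- as.numeric(A %*% F) - b
        sum((F / P)^3) + sum(lam * c_) + 0.5 * mu * sum(c_^2)
      }
      gr <- function(F) {
        c_ <- as.numeric(A %*% F) - b
        3 * F^2 / P^3 + as.numeric(crossprod(A, lam + mu * c_))
      }
      fit <- stats::optim(F, fn, gr, method = "L-BFGS-B",
                          lower = rep(0, n), upper = ub,
                          control = list(maxit = 500, factr = 1e4))
      F <- fit$par
      c_ <- as.numeric(A %*% F) - b
      res <- max(abs(c_))
      if (res < 0.25 * tol) break
      lam <- lam + mu * c_
      if (res > 0.5 * res_prev) mu <- min(mu * 5, 1e10)
      res_prev <- res
    }
    list(F = F, res = max(abs(as.numeric(A %*% F) - b)))
  }

  best <- solve_from(rep(0, n))
  if (n_starts > 1) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1)) {
      cand <- solve_from(stats::runif(n, 0, ub / 4))
      if (cand$res <= tol &&
          (best$res > tol ||
           sum((cand$F / P)^3) < sum((best$F / P)^3) - 1e-9))
        best <- cand
    }
  }
  resid <- as.numeric(A %*% best$F) - b
  names(resid) <- problem$constraint_names
  if (best$res > tol) {
    worst <- problem$constraint_names[which.max(abs(resid))]
    cond <- structure(
      class = c("spineload_infeasible", "error", "condition"),
      list(message = paste0(
        "static optimization infeasible: equality constraint ", worst,
        " violated by ", signif(max(abs(resid)), 3), " N*m (tol ", tol,
        "); consider raising the maximal muscle stress"),
        call = sys.call(-1), residuals = resid))
    stop(cond)
  }
  structure(list(forces = stats::setNames(best$F, rownames(problem$muscles)),
                 cost = sum((best$F / P)^3),
                 residuals = resid,
                 pcsa = P, sigma_max_mpa = problem$sigma_max_mpa),
            class = "static_solution")
}

#' Joint reaction decomposition
#'
#' The load transmitted across each joint is the sum of gravity, external,
#' muscle and ligament forces acting on the superstructure; expressed in
#' the joint frame, compression is the negative superior component,
#' anterior-posterior shear the anterior component and lateral shear the
#' lateral component.
#'
#' @param model a `spine_model` with external loads attached
#' @param pose a `posture`
#' @param forces solved muscle forces (N), in muscle-table order; `NULL`
#'   for the passive/no-muscle decomposition
#' @return data frame: joint, compression_n, ap_shear_n, lateral_shear_n
#' @export
joint_reactions <- function(model, pose, forces = NULL) {
  tf <- pose_model(model, pose)
  mus <- model$muscles
  if (is.null(forces)) forces <- numeric(nrow(mus))
  jn_all <- names(model$joints)
  out <- data.frame(joint = jn_all, compression_n = 0, ap_shear_n = 0,
                    lateral_shear_n = 0)
  po <- lapply(seq_len(nrow(mus)), function(i)
    apply_transform(tf[[mus$origin_body[i]]],
                    c(mus$ox[i], mus$oy[i], mus$oz[i])))
  pi_ <- lapply(seq_len(nrow(mus)), function(i)
    apply_transform(tf[[mus$insertion_body[i]]],
                    c(mus$ix[i], mus$iy[i], mus$iz[i])))
  for (k in seq_along(jn_all)) {
    jn <- jn_all[k]
    j <- model$joints[[jn]]
    super <- superstructure(jn)
    Ftot <- c(0, 0, 0)
    for (bn in super)
      Ftot <- Ftot + c(0, -model$bodies[[bn]]$mass_kg * GRAVITY_MS2, 0)
    for (ex in model$external)
      if (ex$body %in% super) Ftot <- Ftot + ex$force_n
    for (i in seq_len(nrow(mus))) {
      if (forces[i] <= 0) next
      o_in <- mus$origin_body[i] %in% super
      i_in <- mus$insertion_body[i] %in% super
      if (o_in == i_in) next
      pull <- if (o_in) unitv(pi_[[i]] - po[[i]]) else unitv(po[[i]] - pi_[[i]])
      Ftot <- Ftot + forces[i] * pull
    }
    for (lig in model$ligaments) {
      if (!lig_crossing(lig, super)) next
      Ftot <- Ftot + lig_force_on_super(lig, tf, super)$force
    }
    Rp <- tf[[j$parent]][1:3, 1:3] %*% j$R
    loc <- as.numeric(t(Rp) %*% Ftot)              # (anterior, superior, lateral)
    out$compression_n[k] <- -loc[2]
    out$ap_shear_n[k] <- loc[1]
    out$lateral_shear_n[k] <- loc[3]
  }
  out
}

#' Normalize compression forces to the upright-standing case
#'
#' @param reactions named list of reaction tables from [joint_reactions()],
#'   containing an entry named "standing"
#' @return data frame: joint, one column per case with
#'   compression / standing compression
#' @export
normalize_to_standing <- function(reactions) {
  if (!"standing" %in% names(reactions))
    stop("normalization requires a case named 'standing'")
  std <- reactions$standing
  if (any(std$compression_n == 0))
    stop("zero standing compression at joint ",
         paste(std$joint[std$compression_n == 0], collapse = ", "))
  out <- data.frame(joint = std$joint)
  for (nm in names(reactions))
    out[[nm]] <- reactions[[nm]]$compression_n / std$compression_n
  out
}

#' Ligament utilization in a posture
#'
#' Ligament force normalized to the force at the end of the linear region
#' (`F / F_B`); values above 1 are supra-physiological.
#'
#' @param model a `spine_model`
#' @param pose a `posture`
#' @return data frame: ligament, joint, length_mm, force_n, utilization
#' @export
ligament_utilization <- function(model, pose) {
  tf <- pose_model(model, pose)
  rows <- lapply(model$ligaments, function(lig) {
    pa <- apply_transform(tf[[lig$body_a]], lig$attach_a)
    pb <- apply_transform(tf[[lig$body_b]], lig$attach_b)
    l <- sqrt(sum((pa - pb)^2))
    F <- ligament_force(lig, l)
    data.frame(ligament = lig$name, joint = lig$level, length_mm = l,
               force_n = F, utilization = F / lig$F_B)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a battery of load cases
#'
#' For each case: attach the external loads, add the imposed flexion to the
#' neutral posture, solve the static optimization (retrying once with the
#' relaxed 1 MPa muscle-stress bound if 0.6 MPa is infeasible, mirroring
#' the two configured bounds), and decompose the joint reactions.
#'
#' @param model a `spine_model`
#' @param cases named list of `load_case` (default [default_load_cases()])
#' @param neutral neutral-stance `posture` (computed if `NULL`)
#' @param sigma_max_mpa primary and fallback maximal muscle stress, MPa
#' @param tol moment tolerance, N*m
#' @return list: `solutions`, `reactions`, `normalized`, `utilization`,
#'   `postures`, `neutral`
#' @export
simulate_load_cases <- function(model, cases = default_load_cases(),
                                neutral = NULL,
                                sigma_max_mpa = c(0.6, 1.0), tol = 0.1) {
  if (is.null(neutral)) neutral <- neutral_posture(model)
  sols <- list(); reacts <- list(); utils <- list(); poses <- list()
  for (nm in names(cases)) {
    case <- cases[[nm]]
    m <- apply_load_case(model, case)
    pose <- posture_add(neutral, flexion_posture(model,
                                                 case$trunk_flexion_deg))
    sol <- NULL
    for (sm in sigma_max_mpa) {
      prob <- build_problem(m, pose, sigma_max_mpa = sm)
      sol <- tryCatch(solve_static(prob, tol = tol),
                      spineload_infeasible = function(e) e)
      if (!inherits(sol, "condition")) break
    }
    if (inherits(sol, "condition")) stop(sol)
    sols[[nm]] <- sol
    reacts[[nm]] <- joint_reactions(m, pose, sol$forces)
    utils[[nm]] <- ligament_utilization(m, pose)
    poses[[nm]] <- pose
  }
  list(solutions = sols, reactions = reacts,
       normalized = normalize_to_standing(reacts),
       utilization = utils, postures = poses, neutral = neutral)
}
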