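# Nonlinear ligament force-length law: slack below the initial length,
# power-law toe region, then linear up to the end of the physiological
# range.  Strain-based breakpoints guarantee uniform preloads across the
# segments of one ligamentous structure, and the toe-region coefficient is
# constructed so the law is C1-continuous at the toe-to-linear transition.

#' Derive the full parameter set of one ligament segment
#'
#' From the raw inputs (pre-strain, breakpoint strains and whole-ligament
#' breakpoint forces, number of parallel components, and the attachment
#' geometry in neutral posture) all derived quantities are computed:
#' slack length `l_0 = (1 - eps_pre) * l_neut`, per-component breakpoint
#' forces `F_A/n`, breakpoint lengths `l_A/B = (1 + eps_A/B) * l_0`, linear
#' stiffness `K_lin`, tangent-intercept strain `eps_lin`, toe exponent
#' `exp_nll = eps_A / eps_lin` and toe coefficient `K_nl`.
#'
#' @param name ligament system name (ALL, PLL, LF, ISL, SSL)
#' @param level joint label the segment spans (e.g. "L4/L5")
#' @param attach_a,attach_b attachment points in neutral posture, mm
#'   (a = superior, b = inferior)
#' @param n number of parallel components
#' @param eps_pre pre-strain in neutral posture (may be negative)
#' @param eps_A,eps_B breakpoint strains (toe end, linear end)
#' @param F_A,F_B whole-ligament forces at the breakpoints, N
#' @return object of class `ligament_element`
#' @export
derive_ligament_params <- function(name, level, attach_a, attach_b, n,
                                   eps_pre, eps_A, eps_B, F_A, F_B) {
  if (eps_A >= eps_B || F_A >= F_B)
    stop("ligament breakpoints must satisfy eps_A < eps_B and F_A < F_B")
  if (eps_A <= 0 || n < 1) stop("eps_A must be positive and n >= 1")
  l_neut <- sqrt(sum((attach_a - attach_b)^2))
  if (l_neut <= 0) stop("coincident ligament attachments")
  l_0 <- (1 - eps_pre) * l_neut
  F_A_n <- F_A / n; F_B_n <- F_B / n
  l_A <- (1 + eps_A) * l_0; l_B <- (1 + eps_B) * l_0
  K_lin <- (F_B_n - F_A_n) / (l_B - l_A)
  eps_lin <- F_A_n / (K_lin * l_0)
  exp_nll <- eps_A / eps_lin
  if (exp_nll < 1)
    stop("invalid ligament breakpoints: the toe-region secant stiffness ",
         "F_A/eps_A exceeds the linear stiffness (exp_nll = ",
         signif(exp_nll, 3), " < 1); increase F_B or eps_A")
  K_nl <- F_A_n / (eps_A * l_0)^exp_nll
  structure(list(name = name, level = level,
                 attach_a = attach_a, attach_b = attach_b,
                 n = n, l_neut = l_neut, eps_pre = eps_pre,
                 eps_A = eps_A, eps_B = eps_B, F_A = F_A, F_B = F_B,
                 l_0 = l_0, F_A_n = F_A_n, F_B_n = F_B_n,
                 l_A = l_A, l_B = l_B, K_lin = K_lin,
                 eps_lin = eps_lin, exp_nll = exp_nll, K_nl = K_nl),
            class = "ligament_element")
}

#' Elastic ligament force at a given length
#'
#' Piecewise law per parallel component: zero below the slack length,
#' `K_nl * (l - l_0)^exp_nll` in the toe region up to `l_A`, then
#' `F_A_n + K_lin * (l - l_A)` in the linear region.  The returned value is
#' the whole-ligament force (components times `n`).  Continuous with
#' continuous first derivative at `l_A` by construction.
#'
#' @param lig a `ligament_element`
#' @param l current length(s), mm (vectorized)
#' @return force(s), N (non-negative, non-decreasing in `l`)
#' @export
ligament_force <- function(lig, l) {
  if (any(l < 0)) stop("ligament length must be non-negative")
  f <- numeric(length(l))
  toe <- l > lig$l_0 & l <= lig$l_A
  lin <- l > lig$l_A
  f[toe] <- lig$K_nl * (l[toe] - lig$l_0)^lig$exp_nll
  f[lin] <- lig$F_A_n + lig$K_lin * (l[lin] - lig$l_A)
  f * lig$n
}

#' Load the default ligament parameter table
#'
#' Reads `extdata/ligaments.json`: five ligament systems (ALL, PLL, LF,
#' ISL, SSL) with pre-strains, breakpoint strains/forces, parallel-component
#' counts and attachment landmark names.
#' @return named list of per-system parameter lists
#' @export
default_ligament_params <- function() {
  jsonlite::read_json(system.file("extdata", "ligaments.json",
                                  package = "spineload"),
                      simplifyVector = TRUE)$systems
}

#' Lumped intervertebral disc element
#'
#' @param level joint label
#' @param neutral_zone_deg named (frontal, axial, sagittal) rotation range
#'   with no resistive moment, degrees
#' @param stiffness_nm_per_deg named rotational stiffness beyond the
#'   neutral zone, N*m/deg
#' @return object of class `disc_element`
#' @export
disc_element <- function(level,
                         neutral_zone_deg = c(frontal = 1.5, axial = 1,
                                              sagittal = 1.5),
                         stiffness_nm_per_deg = c(frontal = 2.2, axial = 3,
                                                  sagittal = 1.8)) {
  stopifnot(all(neutral_zone_deg >= 0), all(stiffness_nm_per_deg >= 0))
  structure(list(level = level,
                 neutral_zone_deg = neutral_zone_deg,
                 stiffness_nm_per_deg = stiffness_nm_per_deg),
            class = "disc_element")
}

#' Restoring disc moment for a given intervertebral rotation
#'
#' Zero inside the neutral zone; beyond it the moment grows linearly with
#' the exceedance and opposes the rotation (odd function per axis).
#'
#' @param disc a `disc_element`
#' @param rotation_deg named (frontal, axial, sagittal) rotation, degrees
#' @return named restoring moments, N*m (sign opposite to the rotation)
#' @export
disc_moment <- function(disc, rotation_deg) {
  ax <- names(disc$neutral_zone_deg)
  th <- rotation_deg[ax]
  exceed <- pmax(0, abs(th) - disc$neutral_zone_deg)
  m <- -sign(th) * disc$stiffness_nm_per_deg * exceed
  stats::setNames(as.numeric(m), ax)
}

#' Load the default disc stiffness table
#' @return list with `neutral_zone_deg` and `stiffness_nm_per_deg`
#' @export
default_disc_params <- function() {
  jsonlite::read_json(system.file("extdata", "discs.json",
                                  package = "spineload"),
                      simplifyVector = TRUE)$default
}
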