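# Parametric synthetic spine: stacked vertebrae (elliptic-cylinder body plus
# box-shaped arch, spinous and transverse processes) with configurable
# sagittal and frontal curvature, plus a surrounding torso intensity volume
# with lung / fat / soft-tissue compartments.  Every downstream stage of the
# pipeline is testable against this generator's analytic ground truth.

SUBREGION_CODES <- c(body = 1L, arch = 2L, spinous_process = 3L,
                     transverse_left = 4L, transverse_right = 5L)

#' Parameters of the synthetic spine generator
#'
#' Defaults reproduce a mildly lordotic, kyphotic adult alignment
#' (lumbar lordosis 29 deg, thoracic kyphosis 31 deg, no scoliosis) at 2 mm
#' isotropic voxels.
#'
#' @param n_thoracic,n_lumbar vertebra counts (12 and 5)
#' @param vertebra_height vertebral body height, mm
#' @param vertebra_width vertebral body width (lateral), mm
#' @param disc_height intervertebral disc height, mm
#' @param lumbar_lordosis_deg sagittal L1-S1 curvature, degrees
#' @param thoracic_kyphosis_deg sagittal T1-T12 curvature, degrees
#' @param cobb_deg frontal-plane thoracic curvature, degrees
#' @param torso_fat_fraction fraction of the torso cross-section occupied by
#'   the subcutaneous fat shell, in [0, 1]
#' @param voxel_size isotropic voxel edge, mm
#' @param seed integer seed (only consumed when `noise_sd > 0`)
#' @param noise_sd Gaussian intensity jitter (HU) added to the tissue
#'   volume; 0 disables it
#' @return object of class `spine_params`
#' @export
spine_params <- function(n_thoracic = 12, n_lumbar = 5,
                         vertebra_height = 22, vertebra_width = 42,
                         disc_height = 6,
                         lumbar_lordosis_deg = 29,
                         thoracic_kyphosis_deg = 31,
                         cobb_deg = 0,
                         torso_fat_fraction = 0.3,
                         voxel_size = 2, seed = 1L, noise_sd = 0) {
  p <- list(n_thoracic = as.integer(n_thoracic),
            n_lumbar = as.integer(n_lumbar),
            vertebra_height = vertebra_height,
            vertebra_width = vertebra_width,
            disc_height = disc_height,
            lumbar_lordosis_deg = lumbar_lordosis_deg,
            thoracic_kyphosis_deg = thoracic_kyphosis_deg,
            cobb_deg = cobb_deg,
            torso_fat_fraction = torso_fat_fraction,
            voxel_size = voxel_size, seed = as.integer(seed),
            noise_sd = noise_sd)
  with(p, {
    stopifnot(n_thoracic >= 2, n_lumbar >= 2,
              vertebra_height > 0, vertebra_width > 0, disc_height > 0,
              voxel_size > 0,
              torso_fat_fraction >= 0, torso_fat_fraction <= 1)
    if (any(abs(c(lumbar_lordosis_deg, thoracic_kyphosis_deg, cobb_deg)) > 90))
      stop("curvature angles must lie in [-90, 90] degrees")
  })
  structure(p, class = "spine_params")
}

#' Named generator presets
#'
#' `straight` has zero curvature everywhere; `lordotic` the default sagittal
#' alignment; `scoliotic` adds an 18 degree frontal thoracic curve.
#'
#' @param preset one of "straight", "lordotic", "scoliotic"
#' @param ... overrides passed on to [spine_params()]
#' @return a `spine_params`
#' @export
spine_preset <- function(preset = c("straight", "lordotic", "scoliotic"),
                         ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    straight  = list(lumbar_lordosis_deg = 0, thoracic_kyphosis_deg = 0,
                     cobb_deg = 0),
    lordotic  = list(lumbar_lordosis_deg = 29, thoracic_kyphosis_deg = 31,
                     cobb_deg = 0),
    scoliotic = list(lumbar_lordosis_deg = 29, thoracic_kyphosis_deg = 31,
                     cobb_deg = 18))
  do.call(spine_params, utils::modifyList(base, list(...)))
}

# Per-body placement: level names, world centres, rotations, dimensions.
# Sagittal tilt is distributed linearly over the lumbar levels (sacrum ->
# L1 spans the lordosis angle) and the thoracic levels (T12 -> T1 spans the
# kyphosis angle, opposite curvature sense); frontal tilt spans the Cobb
# angle over the thoracic levels.  Tilts are therefore recoverable as
# endplate-line angles of the boundary vertebrae.
spine_layout <- function(params) {
  p <- params
  nT <- p$n_thoracic; nL <- p$n_lumbar
  a <- p$lumbar_lordosis_deg
  b <- p$thoracic_kyphosis_deg
  g <- p$cobb_deg
  levels <- c(paste0("T", seq_len(nT)), paste0("L", seq_len(nL)), "sacrum")
  n_bodies <- nT + nL + 1
  h <- rep(p$vertebra_height, n_bodies)
  h[n_bodies] <- 1.8 * p$vertebra_height            # sacrum block

  # sagittal tilt psi (positive = anterior lean) and frontal tilt zeta,
  # indexed bottom (sacrum) to top (T1)
  psi <- numeric(n_bodies); zeta <- numeric(n_bodies)
  lumbar_idx <- 0:nL                                 # sacrum, L5 ... L1
  psi[n_bodies - lumbar_idx] <- a / 2 - a * lumbar_idx / nL
  thoracic_j <- 0:(nT - 1)                           # T12 ... T1
  psi[nT - thoracic_j] <- -a / 2 + b * thoracic_j / (nT - 1)
  zeta[nT - thoracic_j] <- -g / 2 + g * thoracic_j / (nT - 1)

  centers <- matrix(0, n_bodies, 3)
  rot <- vector("list", n_bodies)
  for (i in seq_len(n_bodies)) rot[[i]] <- rot_x(zeta[i]) %*% rot_z(-psi[i])
  # stack bottom-up from the sacrum at the origin
  for (i in seq(n_bodies - 1, 1)) {
    step <- (h[i] + h[i + 1]) / 2 + p$disc_height
    pm <- (psi[i] + psi[i + 1]) / 2
    zm <- (zeta[i] + zeta[i + 1]) / 2
    dir <- as.numeric(rot_x(zm) %*% rot_z(-pm) %*% c(0, 1, 0))
    centers[i, ] <- centers[i + 1, ] + step * dir
  }
  list(levels = levels, centers = centers, rotations = rot,
       heights = h, psi = psi, zeta = zeta,
       a_x = 0.375 * p$vertebra_width, a_z = 0.5 * p$vertebra_width)
}

# Local-coordinate subregion membership for one vertebra.  `pts` is an
# n x 3 matrix in the vertebra frame (origin at body centre, +x anterior,
# +y superior, +z left).  Returns integer codes (0 outside).
vertebra_subregions_local <- function(pts, h, a_x, a_z, sacrum = FALSE) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  code <- integer(length(x))
  if (sacrum) {
    blk <- abs(x) <= 30 & abs(z) <= 35 & abs(y) <= h / 2
    sp <- x >= -45 & x < -30 & abs(z) <= 4 & abs(y) <= 0.3 * h
    code[sp] <- SUBREGION_CODES[["spinous_process"]]
    code[blk] <- SUBREGION_CODES[["body"]]
    return(code)
  }
  cw <- 9; pw <- cw + 6                       # canal and pedicle half-widths
  x_arch0 <- -a_x - 16; x_can0 <- -a_x - 10
  body <- (x / a_x)^2 + (z / a_z)^2 <= 1 & abs(y) <= h / 2
  canal <- x >= x_can0 & x <= 0 & abs(z) <= cw
  arch <- x >= x_arch0 & x <= -4 & abs(z) <= pw & abs(y) <= 0.35 * h &
    !canal & !body
  spin <- x >= x_arch0 - 20 & x < x_arch0 & abs(z) <= 4 & abs(y) <= 0.3 * h
  tvl <- x >= x_can0 & x <= -a_x - 2 & z > pw & z <= pw + 18 & abs(y) <= 3.5
  tvr <- x >= x_can0 & x <= -a_x - 2 & z < -pw & z >= -pw - 18 & abs(y) <= 3.5
  code[tvl] <- SUBREGION_CODES[["transverse_left"]]
  code[tvr] <- SUBREGION_CODES[["transverse_right"]]
  code[spin] <- SUBREGION_CODES[["spinous_process"]]
  code[arch] <- SUBREGION_CODES[["arch"]]
  code[body] <- SUBREGION_CODES[["body"]]
  code
}

# torso cross-section ellipse (constant over the spine's height); sized so
# the default torso mass corresponds to a ~70 kg adult
torso_section <- function(layout) {
  list(center_x = mean(layout$centers[, 1]) + 45, center_z = 0,
       rx = 125, rz = 155)
}

#' Generate synthetic instance and subregion label volumes
#'
#' Vertebrae T1..T12 and L1..L5 plus a sacrum block are rasterized on a
#' common grid whose affine is diagonal (axis-aligned, `voxel_size` mm).
#' Instance labels run 1 (T1) .. 17 (L5), 18 (sacrum); subregion labels use
#' the codes in `SUBREGION_CODES`.  The output is deterministic for a fixed
#' parameter set.
#'
#' @param params a [spine_params()]
#' @param max_grid maximum allowed voxels per axis (guards against
#'   accidentally tiny `voxel_size`)
#' @return list with elements `instances` and `subregions`
#'   (both `labeled_volume`), plus `layout` (ground-truth placement)
#' @export
generate_spine_volume <- function(params, max_grid = 640) {
  stopifnot(inherits(params, "spine_params"))
  lay <- spine_layout(params)
  tor <- torso_section(lay)
  vs <- params$voxel_size

  # world bounds: spine bodies (+processes) union torso ellipse
  lo <- c(tor$center_x - tor$rx, min(lay$centers[, 2]) - lay$heights[length(lay$heights)],
          tor$center_z - tor$rz) - 4 * vs
  hi <- c(tor$center_x + tor$rx, max(lay$centers[, 2]) + lay$heights[1],
          tor$center_z + tor$rz) + 4 * vs
  # snap the origin to the voxel lattice so the sagittal midplane z = 0
  # falls on voxel centres: left/right rasterization then mirrors exactly
  lo <- vs * floor(lo / vs)
  dims <- ceiling((hi - lo) / vs) + 1
  if (any(dims > max_grid))
    stop("requested voxel grid (", paste(dims, collapse = "x"),
         ") exceeds the ", max_grid, "-voxel sizing limit; ",
         "increase voxel_size")
  affine <- diag(c(vs, vs, vs, 1)); affine[1:3, 4] <- lo

  inst <- array(0L, dim = dims)
  subr <- array(0L, dim = dims)
  n_bodies <- length(lay$levels)
  half_ext <- c(lay$a_x + 40, 0, lay$a_z + 28)  # local bbox half-extents
  for (i in seq_len(n_bodies)) {
    sac <- lay$levels[i] == "sacrum"
    h <- lay$heights[i]
    he <- half_ext; he[2] <- h / 2 + vs
    if (sac) he <- c(50, h / 2 + vs, 40)
    # world bbox of the rotated local box
    corners <- as.matrix(expand.grid(c(-1, 1) * he[1], c(-1, 1) * he[2],
                                     c(-1, 1) * he[3]))
    wc <- sweep(corners %*% t(lay$rotations[[i]]), 2, lay$centers[i, ], "+")
    i0 <- pmax(1, floor((apply(wc, 2, min) - lo) / vs))
    i1 <- pmin(dims, ceiling((apply(wc, 2, max) - lo) / vs) + 2)
    ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
    grid <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
    w <- sweep((grid - 1) * vs, 2, lo, "+")
    loc <- sweep(w, 2, lay$centers[i, ]) %*% lay$rotations[[i]]
    code <- vertebra_subregions_local(loc, h, lay$a_x, lay$a_z, sacrum = sac)
    sel <- code > 0
    if (any(sel)) {
      lin <- grid[sel, 1] + (grid[sel, 2] - 1) * dims[1] +
        (grid[sel, 3] - 1) * dims[1] * dims[2]
      inst[lin] <- i
      subr[lin] <- code[sel]
    }
  }
  lm_inst <- stats::setNames(seq_len(n_bodies), lay$levels)
  out <- list(
    instances = labeled_volume(inst, affine, lm_inst),
    subregions = labeled_volume(subr, affine, SUBREGION_CODES),
    layout = lay)
  class(out) <- "synthetic_spine"
  out
}

#' Generate the surrounding torso intensity volume
#'
#' Adds disjoint lung, subcutaneous fat and soft-tissue compartments around
#' the bone voxels of `instances` on the same grid.  Intensities are placed
#' at the centres of the default classifier windows (lung -800, fat -100,
#' soft +40 HU); bone voxels get +700 HU.  Compartments never overlap bone.
#'
#' @param params the [spine_params()] used for the spine
#' @param instances instance label volume from [generate_spine_volume()]
#' @return intensity `labeled_volume`; attribute `ground_truth` holds the
#'   per-tissue voxel counts
#' @export
generate_tissue_volume <- function(params, instances) {
  stopifnot(inherits(params, "spine_params"),
            inherits(instances, "labeled_volume"))
  lay <- spine_layout(params)
  tor <- torso_section(lay)
  dims <- dim(instances$voxels)
  vs <- voxel_spacing(instances)
  lo <- instances$affine[1:3, 4]

  xw <- lo[1] + (seq_len(dims[1]) - 1) * vs[1]
  yw <- lo[2] + (seq_len(dims[2]) - 1) * vs[2]
  zw <- lo[3] + (seq_len(dims[3]) - 1) * vs[3]

  y_lo <- min(lay$centers[, 2]) - lay$heights[length(lay$heights)] / 2
  y_hi <- max(lay$centers[, 2]) + lay$heights[1] / 2
  in_y <- yw >= y_lo & yw <= y_hi
  # tilted end vertebrae can overhang the nominal span; every slice that
  # contains bone must receive intensities
  in_y <- in_y | apply(instances$voxels > 0, 2, any)

  # elliptical torso mask per axial slice (constant section)
  ex <- (xw - tor$center_x) / tor$rx
  ez <- (zw - tor$center_z) / tor$rz
  r2 <- outer(ex^2, ez^2, "+")                     # nx x nz
  torso2d <- r2 <= 1
  s_in <- sqrt(max(0, 1 - params$torso_fat_fraction))
  core2d <- r2 <= s_in^2

  vol <- array(-1024, dim = dims)                  # air background
  tissue <- array(0L, dim = dims)                  # ground-truth classes
  bone <- instances$voxels > 0

  # lungs: two ellipsoids in the upper thoracic span
  nT <- params$n_thoracic
  t_top <- lay$centers[1, 2]; t_bot <- lay$centers[nT, 2]
  lung_cy <- t_bot + 0.55 * (t_top - t_bot)
  lung_ry <- 0.32 * (t_top - t_bot)
  lung_cx <- tor$center_x + 10
  lungs2d_fun <- function(zc) {
    outer(((xw - lung_cx) / 50)^2, ((zw - zc) / 42)^2, "+")
  }
  lungL <- lungs2d_fun(58); lungR <- lungs2d_fun(-58)

  for (j in which(in_y)) {
    sl_fat <- torso2d & !core2d
    sl_soft <- core2d
    dy2 <- ((yw[j] - lung_cy) / lung_ry)^2
    sl_lung <- matrix(FALSE, dims[1], dims[3])
    if (dy2 < 1) sl_lung <- (lungL + dy2 < 1) | (lungR + dy2 < 1)
    sl_lung <- sl_lung & sl_soft
    sl_soft <- sl_soft & !sl_lung
    b <- bone[, j, ]
    sl_fat <- sl_fat & !b; sl_soft <- sl_soft & !b; sl_lung <- sl_lung & !b
    sl <- array(0L, dim = c(dims[1], dims[3]))
    sl[sl_lung] <- 1L; sl[sl_fat] <- 2L; sl[sl_soft] <- 3L
    tissue[, j, ] <- sl
    v <- array(-1024, dim = c(dims[1], dims[3]))
    v[sl_lung] <- -800; v[sl_fat] <- -100; v[sl_soft] <- 40
    v[b] <- 700
    vol[, j, ] <- v
  }
  if (any(tissue > 0 & bone))
    stop("tissue compartment overlaps bone labels")  # internal consistency
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    nz <- vol > -1024
    vol[nz] <- vol[nz] + stats::rnorm(sum(nz), 0, params$noise_sd)
  }
  out <- labeled_volume(vol, instances$affine)
  attr(out, "ground_truth") <- list(
    voxel_counts = c(lung = sum(tissue == 1L), fat = sum(tissue == 2L),
                     soft = sum(tissue == 3L)),
    tissue_labels = tissue)
  out
}

#' Analytic toy muscle-redundancy problems with attached solutions
#'
#' Small fully specified static-optimization problems used as oracles for
#' the solver: the closed-form optimum of the cubed-stress cost under the
#' stated moment constraint is attached as `$solution`.
#'
#' @param name one of "single_muscle", "antagonist_pair", "two_agonists"
#' @return an `optimization_problem` (see [solve_static()]) with a
#'   `$solution` element (forces, N)
#' @export
make_toy_problem <- function(name = c("single_muscle", "antagonist_pair",
                                      "two_agonists")) {
  name <- match.arg(name)
  prob <- switch(name,
    single_muscle = list(
      moment_arms = matrix(0.05, 1, 1),
      target = 10, pcsa = 10,
      solution = 200),                       # F = M / r
    antagonist_pair = list(
      moment_arms = matrix(c(0.05, -0.05), 1, 2),
      target = 10, pcsa = c(10, 10),
      solution = c(200, 0)),                 # co-contraction only adds cost
    two_agonists = list(
      moment_arms = matrix(c(0.05, 0.05), 1, 2),
      target = 10, pcsa = c(10, 20),
      # KKT: F_i proportional to PCSA_i^(3/2); F1 + F2 = M / r
      solution = 200 * c(1, 2^1.5) / (1 + 2^1.5)))
  structure(list(moment_arms = prob$moment_arms,
                 target = prob$target,
                 pcsa = prob$pcsa,
                 sigma_max_mpa = 0.6,
                 constraint_names = paste0("c", seq_along(prob$target)),
                 name = name,
                 solution = prob$solution),
            class = "optimization_problem")
}

#' Write a generated synthetic spine to disk
#'
#' Writes instance and subregion NIfTI volumes with JSON sidecars carrying
#' the label maps and the ground-truth layout (levels, centres, tilts).
#'
#' @param spine result of [generate_spine_volume()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synthetic_spine <- function(spine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lay <- spine$layout
  gt <- list(levels = lay$levels,
             centers = apply(lay$centers, 1, function(r) r, simplify = FALSE),
             sagittal_tilt_deg = lay$psi, frontal_tilt_deg = lay$zeta)
  write_labeled_volume(spine$instances, file.path(dir, "instances.nii.gz"),
                       sidecar = list(ground_truth = gt))
  write_labeled_volume(spine$subregions, file.path(dir, "subregions.nii.gz"))
  invisible(dir)
}
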