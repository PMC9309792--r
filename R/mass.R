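# Tissue classification from CT-style intensities, partition into
# per-vertebral-level segments with mass and centre of mass, and scaling of
# the generic (non-imaged) body segments.

#' Tissue density table (g/cm^3)
#'
#' Defaults: lung 0.25, fat 0.96, remaining soft tissue 1.06, bone 1.5.
#'
#' @param lung,fat,soft,bone densities in g/cm^3
#' @return named numeric vector of class `density_table`
#' @export
density_table <- function(lung = 0.25, fat = 0.96, soft = 1.06,
                          bone = 1.5) {
  d <- c(lung = lung, fat = fat, soft = soft, bone = bone)
  if (any(d <= 0)) stop("densities must be positive")
  structure(d, class = "density_table")
}

#' Default Hounsfield-unit classification windows
#'
#' Half-open intervals `[lo, hi)` per tissue; configurable because scanners
#' and calibrations differ.
#' @return named list of length-2 numeric vectors
#' @export
default_hu_ranges <- function() {
  list(lung = c(-1000, -500), fat = c(-200, -20), soft = c(-20, 150))
}

TISSUE_CODES <- c(lung = 1L, fat = 2L, soft = 3L)

#' Classify torso tissues from an intensity volume
#'
#' Every voxel whose intensity falls inside a tissue window receives that
#' tissue's label; voxels marked as bone in the instance mask are excluded;
#' everything else stays unlabeled (0).
#'
#' @param intensities intensity `labeled_volume`
#' @param ranges named list of `[lo, hi)` intervals (see
#'   [default_hu_ranges()]); must be pairwise disjoint
#' @param instances optional instance mask on the same grid; nonzero voxels
#'   are excluded as bone
#' @return tissue label `labeled_volume` (codes lung 1, fat 2, soft 3)
#' @export
classify_tissues <- function(intensities, ranges = default_hu_ranges(),
                             instances = NULL) {
  stopifnot(all(names(ranges) %in% names(TISSUE_CODES)))
  iv <- do.call(rbind, lapply(ranges, function(r) sort(r)))
  o <- order(iv[, 1])
  if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
    stop("tissue intensity intervals overlap")
  lab <- array(0L, dim = dim(intensities$voxels))
  v <- intensities$voxels
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    lab[v >= r[1] & v < r[2]] <- TISSUE_CODES[[nm]]
  }
  if (!is.null(instances)) lab[instances$voxels > 0] <- 0L
  labeled_volume(lab, intensities$affine, TISSUE_CODES)
}

#' Partition classified tissue into per-vertebral-level segments
#'
#' Each labeled voxel is assigned to the vertebra whose centroid is nearest
#' along the craniocaudal (superior) axis, producing contiguous axial slabs
#' per level.  Per-level mass and centre of mass follow from the density
#' table.
#'
#' @param tissue_labels output of [classify_tissues()]
#' @param geometries named list of `vertebra_geometry` (realigned)
#' @param densities a [density_table()]
#' @return data frame of class `tissue_segments`: level, mass_kg, com
#'   (3 columns, mm), per-tissue volumes (cm^3)
#' @export
assign_to_levels <- function(tissue_labels, geometries,
                             densities = density_table()) {
  if (length(geometries) == 0) stop("no vertebra geometries supplied")
  lv <- names(geometries)
  cy <- vapply(geometries, function(g) g$centroid[2], numeric(1))
  idx <- which(tissue_labels$voxels > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no classified tissue voxels")
  pts <- voxel_to_world(tissue_labels, idx)
  code <- tissue_labels$voxels[tissue_labels$voxels > 0L]
  # nearest centroid along the superior axis via interval bisection of the
  # sorted midpoints (avoids an n-voxels-by-n-levels distance matrix)
  ord <- order(cy)
  bounds <- (cy[ord][-1] + cy[ord][-length(cy)]) / 2
  near <- ord[findInterval(pts[, 2], bounds) + 1L]
  vv_cm3 <- voxel_volume_mm3(tissue_labels) / 1000
  dens <- unclass(densities)[names(TISSUE_CODES)]   # g/cm3, tissue order

  out <- data.frame(level = lv,
                    mass_kg = 0, com_x = NA_real_, com_y = NA_real_,
                    com_z = NA_real_, lung_cm3 = 0, fat_cm3 = 0,
                    soft_cm3 = 0, stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    s <- near == i
    if (!any(s)) next
    cnt <- tabulate(code[s], nbins = 3L)
    vols <- cnt * vv_cm3
    w <- dens[code[s]]                              # per-voxel mass weight
    m_g <- sum(w) * vv_cm3
    out$mass_kg[i] <- m_g / 1000
    out[i, c("com_x", "com_y", "com_z")] <-
      colSums(pts[s, , drop = FALSE] * w) / sum(w)
    out[i, c("lung_cm3", "fat_cm3", "soft_cm3")] <- vols
  }
  class(out) <- c("tissue_segments", class(out))
  out
}

#' Bone mass of one labeled vertebra
#'
#' Voxel volume times the bone density (default 1.5 g/cm^3).
#'
#' @param instances instance `labeled_volume`
#' @param level vertebral level name
#' @param densities a [density_table()]
#' @return mass in kg
#' @export
bone_mass <- function(instances, level, densities = density_table()) {
  id <- unname(instances$label_map[match(level,
                                         names(instances$label_map))])
  if (is.na(id)) stop("level not present in instance labels: ", level)
  n <- sum(instances$voxels == id)
  n * voxel_volume_mm3(instances) / 1000 * densities[["bone"]] / 1000
}

#' Default anthropometric segment-fraction table
#'
#' Segment masses as fractions of whole-body mass, from standard
#' anthropometric reference tables: head plus neck 8.1%, each whole arm
#' 5.0%, trunk 49.7%.  Shipped as an editable JSON config
#' (`extdata/anthropometry.json`).
#' @return list with `fractions` and `reference_stature_m`
#' @export
default_anthropometry <- function() {
  jsonlite::read_json(system.file("extdata", "anthropometry.json",
                                  package = "spineload"),
                      simplifyVector = TRUE)
}

#' Scale generic body segments from stature and torso mass
#'
#' Whole-body mass is inferred from the CT-derived torso mass through the
#' configured trunk fraction; head-neck and per-arm masses are fractions of
#' whole-body mass, and generic geometry scales linearly with stature.
#'
#' @param stature_m body height, m
#' @param torso_mass_kg torso (trunk) mass from the CT partition, kg
#' @param table anthropometric table (see [default_anthropometry()])
#' @return list: `body_mass_kg`, `head_neck_kg`, `arm_kg` (each arm),
#'   `geometry_scale`
#' @export
scale_generic_segments <- function(stature_m, torso_mass_kg,
                                   table = default_anthropometry()) {
  stopifnot(stature_m > 0, torso_mass_kg >= 0)
  fr <- table$fractions
  if (any(unlist(fr) <= 0 | unlist(fr) >= 1))
    stop("anthropometric fractions must lie in (0, 1)")
  if (fr$head_neck + 2 * fr$arm + fr$trunk > 1)
    stop("anthropometric fractions sum above 1")
  body <- torso_mass_kg / fr$trunk
  list(body_mass_kg = body,
       head_neck_kg = fr$head_neck * body,
       arm_kg = fr$arm * body,
       geometry_scale = stature_m / table$reference_stature_m)
}
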