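# Labeled voxel volumes: the common container for instance masks, subregion
# masks and intensity volumes.  World coordinates are obtained through a
# standard NIfTI-style affine mapping 0-based voxel indices to mm.

#' Construct a labeled volume
#'
#' A `labeled_volume` bundles a 3-D voxel grid with a 4x4 voxel-to-world
#' affine (mm) and, for label volumes, a name-to-integer label map.
#'
#' @param voxels 3-D array (integer labels or numeric intensities)
#' @param affine 4x4 voxel-to-world transform; voxel indices are 0-based
#' @param label_map named integer vector mapping label names to voxel values,
#'   or `NULL` for intensity volumes
#' @return object of class `labeled_volume`
#' @export
labeled_volume <- function(voxels, affine, label_map = NULL) {
  stopifnot(length(dim(voxels)) == 3, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  if (!is.null(label_map)) {
    label_map <- as.integer(label_map) |> stats::setNames(names(label_map))
    present <- unique(as.vector(voxels))
    present <- present[present != 0]
    missing <- setdiff(present, label_map)
    if (length(missing))
      stop("voxel values without label_map entry: ",
           paste(missing, collapse = ", "))
  }
  structure(list(voxels = voxels, affine = affine, label_map = label_map),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, voxel size ",
      paste(signif(voxel_spacing(x), 4), collapse = " x "), " mm\n", sep = "")
  if (!is.null(x$label_map))
    cat("  labels: ", paste(names(x$label_map), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Voxel spacing (mm) along each axis
#' @param vol a `labeled_volume`
#' @return numeric length-3
#' @export
voxel_spacing <- function(vol) {
  A <- vol$affine[1:3, 1:3]
  sqrt(colSums(A^2))
}

#' Volume of one voxel in cubic millimetres
#' @param vol a `labeled_volume`
#' @export
voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' World coordinates (mm) of voxel indices
#'
#' @param vol a `labeled_volume`
#' @param idx n x 3 matrix of 1-based voxel indices (as returned by
#'   `which(..., arr.ind = TRUE)`)
#' @return n x 3 matrix of world coordinates
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  apply_transform(vol$affine, idx - 1)
}

#' World coordinates of all voxels equal to a label value
#' @param vol a `labeled_volume`
#' @param value integer voxel value to select
#' @return n x 3 matrix (possibly 0-row)
#' @export
label_points <- function(vol, value) {
  idx <- which(vol$voxels == value, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 3))
  voxel_to_world(vol, idx)
}

#' Apply a rigid transform to a volume's frame
#'
#' The voxel grid is untouched; only the affine is premultiplied, so all
#' world-space computations downstream see the transformed coordinates.
#'
#' @param vol a `labeled_volume`
#' @param transform 4x4 rigid transform
#' @return transformed `labeled_volume`
#' @export
transform_volume <- function(vol, transform) {
  vol$affine <- transform %*% vol$affine
  vol
}

#' Write a labeled volume as NIfTI plus a JSON sidecar
#'
#' @param vol a `labeled_volume`
#' @param path output path ending in `.nii` or `.nii.gz`; the sidecar with
#'   the label map is written next to it with extension `.json`
#' @param sidecar optional extra fields (e.g. ground-truth geometry) to merge
#'   into the sidecar
#' @return `path`, invisibly
#' @export
write_labeled_volume <- function(vol, path, sidecar = list()) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  meta <- c(list(label_map = as.list(vol$label_map)), sidecar)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a labeled volume written by [write_labeled_volume()]
#' @param path NIfTI file path
#' @return a `labeled_volume`
#' @export
read_labeled_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  lm <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp)
    if (!is.null(meta$label_map))
      lm <- stats::setNames(as.integer(unlist(meta$label_map)),
                            names(meta$label_map))
  }
  arr <- array(as.vector(img), dim = dim(img))
  labeled_volume(arr, aff, lm)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
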