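# Small linear-algebra helpers shared across modules.
#
# Model frame convention (right-handed): +X anterior, +Y superior,
# +Z subject-left.  Gravity acts along (0, -1, 0).  Lengths are mm unless a
# function documents otherwise; moments are N*m (attachment coordinates are
# converted mm -> m inside the statics code).

GRAVITY_MS2 <- 9.81

#' Cross product of two 3-vectors
#' @param a,b numeric length-3 vectors
#' @return numeric length-3 vector a x b
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalize a vector to unit length
#' @param v numeric vector
#' @keywords internal
unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5)
    stop("cannot normalize a (near-)zero vector")
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Elementary rotation matrices (angle in degrees)
#' @keywords internal
rot_x <- function(deg) {
  t <- deg2rad(deg); ct <- cos(t); st <- sin(t)
  matrix(c(1, 0, 0,  0, ct, st,  0, -st, ct), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(deg) {
  t <- deg2rad(deg); ct <- cos(t); st <- sin(t)
  matrix(c(ct, st, 0,  -st, ct, 0,  0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary unit axis (Rodrigues), angle in degrees
#' @keywords internal
rot_axis <- function(axis, deg) {
  u <- unitv(axis)
  t <- deg2rad(deg); ct <- cos(t); st <- sin(t)
  ux <- matrix(c(0, u[3], -u[2],  -u[3], 0, u[1],  u[2], -u[1], 0), 3, 3)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

#' Build a 4x4 rigid transform from rotation and translation
#' @keywords internal
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

#' 4x4 transform rotating about a fixed pivot point
#' @keywords internal
rotation_about_point <- function(R, pivot) {
  rigid_transform(R, as.numeric(pivot) - R %*% as.numeric(pivot))
}

#' Apply a 4x4 rigid transform to points
#' @param T 4x4 matrix
#' @param pts numeric 3-vector or n x 3 matrix
#' @keywords internal
apply_transform <- function(T, pts) {
  if (is.null(dim(pts))) {
    as.numeric(T[1:3, 1:3] %*% pts + T[1:3, 4])
  } else {
    sweep(pts %*% t(T[1:3, 1:3]), 2, T[1:3, 4], "+")
  }
}

#' Signed sagittal / frontal tilt of a direction vector, in degrees
#'
#' Sagittal tilt is the angle of the vector's projection into the X-Y
#' (sagittal) plane away from +Y, positive when leaning anterior (+X).
#' Frontal tilt is the analogue in the Z-Y plane, positive toward +Z.
#' @keywords internal
sagittal_tilt_deg <- function(v) rad2deg(atan2(v[1], v[2]))

#' @rdname sagittal_tilt_deg
#' @keywords internal
frontal_tilt_deg <- function(v) rad2deg(atan2(v[3], v[2]))
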