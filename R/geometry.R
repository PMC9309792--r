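# Landmark, joint and alignment extraction from labeled volumes.
#
# All computations run in world millimetres after craniocaudal realignment:
# the T1-L5 centroid line is rotated onto the world vertical (+Y) axis to
# remove the supine/upright posture difference, then per-subregion landmarks
# are found as coordinate extremes, plane sections and shortest-distance
# projections.

LEVEL_ORDER <- c(paste0("T", 1:12), paste0("L", 1:5), "sacrum")

level_index <- function(level) {
  i <- match(level, LEVEL_ORDER)
  if (any(is.na(i))) stop("unknown vertebral level: ",
                          paste(level[is.na(i)], collapse = ", "))
  i
}

#' Instance centroids of every labeled vertebra
#'
#' @param instances instance `labeled_volume`
#' @return matrix with one row per label (rownames = level names), world mm
#' @export
vertebra_centroids <- function(instances) {
  lm <- instances$label_map
  out <- matrix(NA_real_, length(lm), 3,
                dimnames = list(names(lm), c("x", "y", "z")))
  for (i in seq_along(lm)) {
    pts <- label_points(instances, lm[i])
    if (nrow(pts)) out[i, ] <- colMeans(pts)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Rigid transform aligning the T1-L5 centroid line with vertical
#'
#' Returns the rigid (rotation + translation) transform that maps the line
#' from the L5 centroid to the T1 centroid onto the world +Y axis, keeping
#' the L5 centroid fixed.
#'
#' @param centroids matrix with rownames including "T1" and "L5"
#' @return 4x4 rigid transform
#' @export
realign_craniocaudal <- function(centroids) {
  if (!all(c("T1", "L5") %in% rownames(centroids)))
    stop("realignment requires both T1 and L5 centroids")
  c_t1 <- centroids["T1", ]; c_l5 <- centroids["L5", ]
  u <- unitv(c_t1 - c_l5)
  y <- c(0, 1, 0)
  ax <- cross3(u, y)
  s <- sqrt(sum(ax^2)); cth <- sum(u * y)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(-1, 1, -1))   # antiparallel: flip
  } else {
    rot_axis(ax, rad2deg(atan2(s, cth)))
  }
  rotation_about_point(R, c_l5)
}

pick_extreme <- function(pts, coord, which = c("min", "max"),
                         center = NULL) {
  which <- match.arg(which)
  v <- pts[, coord]
  target <- if (which == "min") min(v) else max(v)
  cand <- which(abs(v - target) < 1e-9)
  if (length(cand) > 1) {
    if (is.null(center)) center <- colMeans(pts)
    d2 <- rowSums((pts[cand, , drop = FALSE] -
                     matrix(center, length(cand), 3, byrow = TRUE))^2)
    cand <- cand[which.min(d2)]
  }
  pts[cand[1], ]
}

plane_slab <- function(pts, coord, value, thick) {
  pts[abs(pts[, coord] - value) <= thick / 2, , drop = FALSE]
}

# Project rectangle border points onto the set `pts` by shortest distance.
project_nearest <- function(targets, pts) {
  out <- matrix(NA_real_, nrow(targets), 3)
  for (i in seq_len(nrow(targets))) {
    d2 <- (pts[, 1] - targets[i, 1])^2 + (pts[, 2] - targets[i, 2])^2 +
      (pts[, 3] - targets[i, 3])^2
    out[i, ] <- pts[which.min(d2), ]
  }
  out
}

# shortest-distance pair between the arch anterior border and the posterior
# vertebral-body surface inside one sagittal slab; returns the arch point
arch_attachment_in_slab <- function(arch_pts, body_pts) {
  if (nrow(arch_pts) == 0 || nrow(body_pts) == 0) return(NULL)
  ybins <- round(arch_pts[, 2])
  border <- do.call(rbind, lapply(split(seq_len(nrow(arch_pts)), ybins),
    function(ii) arch_pts[ii[which.min(arch_pts[ii, 1])], ]))
  ybins_b <- round(body_pts[, 2])
  post <- do.call(rbind, lapply(split(seq_len(nrow(body_pts)), ybins_b),
    function(ii) body_pts[ii[which.max(body_pts[ii, 1])], ]))
  d2 <- outer(seq_len(nrow(border)), seq_len(nrow(post)),
              Vectorize(function(i, j) sum((border[i, ] - post[j, ])^2)))
  ij <- arrayInd(which.min(d2), dim(d2))
  border[ij[1], ]
}

#' Extract landmarks and endplate centres for one vertebra
#'
#' Landmarks follow the subregion extreme-value scheme: most posterior /
#' inferior / superior point of the spinous process, most lateral points of
#' the transverse processes, most lateral body points in the horizontal
#' midplane, vertebral-body rim points obtained by fitting an axis-aligned
#' rectangle to the sagittal midplane section and projecting its corner and
#' edge-centre points onto the body surface, and arch attachment points via
#' the shortest distance between the arch's anterior border and the
#' posterior body surface (central slab, repeated shifted left and right).
#'
#' @param subregions subregion `labeled_volume`
#' @param instances instance `labeled_volume` on the same grid
#' @param level vertebral level name ("T1".."L5", "sacrum")
#' @param superior_axis unit vector used to slice endplate layers (usually
#'   the centroid-spline tangent at this vertebra)
#' @return object of class `vertebra_geometry`
#' @export
extract_landmarks <- function(subregions, instances, level,
                              superior_axis = c(0, 1, 0)) {
  id <- unname(instances$label_map[match(level,
                                         names(instances$label_map))])
  if (is.na(id)) stop("level not present in instance labels: ", level)
  sel <- instances$voxels == id
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("instance mask empty for level ", level)
  all_pts <- voxel_to_world(instances, idx)
  codes <- subregions$voxels[sel]
  vs <- max(voxel_spacing(subregions))
  region <- function(name) {
    all_pts[codes == SUBREGION_CODES[[name]], , drop = FALSE]
  }
  need <- function(name, pts) {
    if (nrow(pts) == 0)
      stop("missing landmark source: subregion '", name,
           "' is empty for level ", level)
    pts
  }
  lk <- list()
  body <- need("body", region("body"))
  bc <- colMeans(body)
  centroid <- colMeans(all_pts)

  sp <- region("spinous_process")
  if (nrow(sp)) {
    lk$spinous_posterior <- pick_extreme(sp, 1, "min")
    lk$spinous_inferior <- pick_extreme(sp, 2, "min")
    lk$spinous_superior <- pick_extreme(sp, 2, "max")
  } else if (level != "sacrum") {
    stop("missing landmark source: subregion 'spinous_process' is empty ",
         "for level ", level)
  }
  if (level != "sacrum") {
    tvl <- need("transverse_left", region("transverse_left"))
    tvr <- need("transverse_right", region("transverse_right"))
    lk$transverse_left_lateral <- pick_extreme(tvl, 3, "max")
    lk$transverse_right_lateral <- pick_extreme(tvr, 3, "min")
  }

  # most lateral body points in the horizontal midplane
  hmid <- plane_slab(body, 2, bc[2], 1.2 * vs)
  if (nrow(hmid)) {
    lk$body_left_lateral <- pick_extreme(hmid, 3, "max")
    lk$body_right_lateral <- pick_extreme(hmid, 3, "min")
  }

  # sagittal-midplane rectangle fit and rim projection
  smid <- plane_slab(body, 3, bc[3], 1.2 * vs)
  if (nrow(smid)) {
    xr <- range(smid[, 1]); yr <- range(smid[, 2])
    xm <- mean(xr); ym <- mean(yr)
    border <- rbind(
      body_ant_sup = c(xr[2], yr[2], bc[3]),
      body_ant_inf = c(xr[2], yr[1], bc[3]),
      body_post_sup = c(xr[1], yr[2], bc[3]),
      body_post_inf = c(xr[1], yr[1], bc[3]),
      body_ant_center = c(xr[2], ym, bc[3]),
      body_post_center = c(xr[1], ym, bc[3]),
      body_sup_center = c(xm, yr[2], bc[3]),
      body_inf_center = c(xm, yr[1], bc[3]))
    proj <- project_nearest(border, smid)
    for (i in seq_len(nrow(border))) lk[[rownames(border)[i]]] <- proj[i, ]
  }

  # arch attachment points: central sagittal slab, then shifted left/right
  arch <- region("arch")
  if (nrow(arch)) {
    shift <- 10
    for (nm in c("arch_attach_center", "arch_attach_left",
                 "arch_attach_right")) {
      off <- switch(nm, arch_attach_center = 0, arch_attach_left = shift,
                    arch_attach_right = -shift)
      a <- plane_slab(arch, 3, bc[3] + off, 2.2 * vs)
      b <- plane_slab(body, 3, bc[3] + off, 2.2 * vs)
      p <- arch_attachment_in_slab(a, b)
      if (!is.null(p)) lk[[nm]] <- p
    }
  }

  # Endplate caps.  A vertebral body is wider than tall, so its axis is the
  # smallest-variance principal axis of the voxel cloud (sign fixed by the
  # spline tangent).  The cap surfaces are the body voxels exposed along the
  # grid vertical; fitting each cap as a thin disk (plane via PCA) averages
  # voxel quantization over the cap's full width, giving sub-degree endplate
  # orientations and sub-voxel centres.
  ev <- eigen(stats::cov(body), symmetric = TRUE)
  s <- ev$vectors[, 3]
  if (sum(s * unitv(superior_axis)) < 0) s <- -s
  yy <- as.numeric((body - matrix(bc, nrow(body), 3, byrow = TRUE)) %*% s)

  body_mask <- sel & subregions$voxels == SUBREGION_CODES[["body"]]
  dims <- dim(body_mask)
  open_up <- body_mask
  open_up[, -dims[2], ] <- body_mask[, -dims[2], ] &
    !body_mask[, -1, , drop = FALSE]
  open_dn <- body_mask
  open_dn[, -1, ] <- body_mask[, -1, , drop = FALSE] &
    !body_mask[, -dims[2], , drop = FALSE]
  surf_up <- open_up[sel][codes == SUBREGION_CODES[["body"]]]
  surf_dn <- open_dn[sel][codes == SUBREGION_CODES[["body"]]]
  # Exposed-surface candidates also include staircase voxels on the tilted
  # lateral wall, so restrict to a band near the cap and trim plane-fit
  # outliers before accepting the fit.
  cap_plane <- function(pts, orient) {
    for (iter in 1:3) {
      ctr <- colMeans(pts)
      n <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 3]
      if (sum(n * orient) < 0) n <- -n
      res <- abs(as.numeric(sweep(pts, 2, ctr) %*% n))
      keep <- res <= max(1.5 * vs / (iter + 0.5), 0.8 * vs)
      if (all(keep) || sum(keep) < 12) break
      pts <- pts[keep, , drop = FALSE]
    }
    list(center = ctr, normal = n)
  }
  h_est <- max(yy) - min(yy)
  top <- cap_plane(body[surf_up & yy > max(yy) - 0.22 * h_est, ,
                        drop = FALSE], s)
  bot <- cap_plane(body[surf_dn & yy < min(yy) + 0.22 * h_est, ,
                        drop = FALSE], -s)

  structure(list(level = level,
                 centroid = centroid,
                 body_centroid = bc,
                 endplate_superior_center = top$center,
                 endplate_inferior_center = bot$center,
                 endplate_superior_normal = top$normal,
                 endplate_inferior_normal = bot$normal,
                 landmarks = lk,
                 superior_axis = unitv(top$center - bot$center)),
            class = "vertebra_geometry")
}

#' Intervertebral joint centre
#'
#' Midpoint of the line connecting the superior endplate centre of the
#' inferior vertebra with the inferior endplate centre of the superior
#' vertebra.
#'
#' @param inferior,superior `vertebra_geometry` of two adjacent levels
#' @return 3-vector, mm
#' @export
joint_center <- function(inferior, superior) {
  ii <- level_index(inferior$level); is <- level_index(superior$level)
  if (ii - is != 1L)
    stop("joint_center requires adjacent levels (got ", superior$level,
         " above ", inferior$level, ")")
  (inferior$endplate_superior_center + superior$endplate_inferior_center) / 2
}

# natural cubic spline through centroids (ordered caudal -> cranial),
# parameterized by cumulative chord length; returns position and tangent
# functions of arc parameter
centroid_spline <- function(centroids) {
  if (nrow(centroids) < 4)
    stop("centroid spline requires at least 4 centroids")
  d <- sqrt(rowSums(diff(centroids)^2))
  if (any(d < 1e-9)) stop("degenerate (repeated) centroids")
  t <- c(0, cumsum(d))
  fx <- stats::splinefun(t, centroids[, 1], method = "natural")
  fy <- stats::splinefun(t, centroids[, 2], method = "natural")
  fz <- stats::splinefun(t, centroids[, 3], method = "natural")
  list(t = t,
       pos = function(s) c(fx(s), fy(s), fz(s)),
       tangent = function(s) unitv(c(fx(s, deriv = 1), fy(s, deriv = 1),
                                     fz(s, deriv = 1))))
}

# rotation with columns (anterior, superior, lateral) from a superior
# tangent: anterior = in-sagittal-plane normal of the tangent
frame_from_tangent <- function(tangent) {
  s <- unitv(tangent)
  a <- c(s[2], -s[1], 0)
  if (sqrt(sum(a^2)) < 1e-9)
    stop("tangent lies in the frontal plane; anterior axis undefined")
  a <- unitv(a)
  a <- unitv(a - sum(a * s) * s)       # exact orthogonality
  l <- cross3(a, s)
  R <- cbind(anterior = a, superior = s, lateral = l)
  R
}

#' Intervertebral joint orientation from the centroid spline
#'
#' Fits a natural cubic spline through the vertebral body centroids
#' (ordered caudal to cranial, parameterized by cumulative chord length) and
#' evaluates its tangent where the spline crosses the superior endplate of
#' the inferior vertebra.  Columns of the returned rotation are the
#' anterior, superior and lateral joint axes.
#'
#' @param centroids matrix ordered caudal to cranial (>= 4 rows)
#' @param inferior_row row index of the joint's inferior vertebra
#' @param endplate_offset_mm arc distance from that centroid to its superior
#'   endplate (defaults to 40% of the gap to the next centroid)
#' @return 3x3 rotation, det +1
#' @export
joint_orientation <- function(centroids, inferior_row,
                              endplate_offset_mm = NULL) {
  sp <- centroid_spline(centroids)
  if (inferior_row >= nrow(centroids) || inferior_row < 1)
    stop("inferior_row must index a non-terminal centroid")
  if (is.null(endplate_offset_mm))
    endplate_offset_mm <-
      0.4 * (sp$t[inferior_row + 1] - sp$t[inferior_row])
  frame_from_tangent(sp$tangent(sp$t[inferior_row] + endplate_offset_mm))
}

#' Sagittal and frontal alignment metrics
#'
#' Angles between the endplate lines of the boundary vertebrae: lumbar
#' lordosis (L1 superior vs sacral superior endplate), thoracic kyphosis
#' (T1 superior vs T12 inferior endplate) in the sagittal plane, and the
#' frontal Cobb angle over the thoracic spine.  Endplate line orientation is
#' taken from the vertebra's endplate-centre axis.  All values are signed
#' degrees; magnitudes correspond to the clinical angles.
#'
#' @param geometries named list of `vertebra_geometry` (must contain T1,
#'   T12, L1 and sacrum)
#' @return list with `lordosis_deg`, `kyphosis_deg`, `cobb_deg`
#' @export
measure_alignment <- function(geometries) {
  for (lv in c("T1", "T12", "L1", "sacrum"))
    if (is.null(geometries[[lv]]))
      stop("alignment requires boundary vertebra ", lv)
  sup <- function(g) g$endplate_superior_normal
  inf <- function(g) -g$endplate_inferior_normal     # pointing superior
  list(lordosis_deg = sagittal_tilt_deg(sup(geometries$sacrum)) -
         sagittal_tilt_deg(sup(geometries$L1)),
       kyphosis_deg = sagittal_tilt_deg(sup(geometries$T1)) -
         sagittal_tilt_deg(inf(geometries$T12)),
       cobb_deg = frontal_tilt_deg(sup(geometries$T1)) -
         frontal_tilt_deg(inf(geometries$T12)))
}

#' Full geometry extraction pipeline for a labeled spine
#'
#' Computes instance centroids, realigns craniocaudally, extracts per-level
#' landmarks (using centroid-spline tangents as local superior axes), joint
#' centres and orientations for T12/L1 through L5/S1, and alignment metrics.
#'
#' @param instances,subregions matching `labeled_volume`s
#' @param realign apply craniocaudal realignment (default TRUE)
#' @return list with `geometries` (named list), `joints` (named list of
#'   `name`, `origin`, `R`), `alignment`, `transform`, `centroids`
#' @export
extract_geometry <- function(instances, subregions, realign = TRUE) {
  cen <- vertebra_centroids(instances)
  transform <- if (realign) realign_craniocaudal(cen) else diag(4)
  instances <- transform_volume(instances, transform)
  subregions <- transform_volume(subregions, transform)
  cen <- apply_transform(transform, cen)

  # vertebral-body centroids drive the spline (instance centroids are
  # biased posteriorly by the processes, and differently so for the sacrum)
  body_code <- SUBREGION_CODES[["body"]]
  bcen <- cen
  for (lv in rownames(cen)) {
    sel <- instances$voxels == instances$label_map[[lv]] &
      subregions$voxels == body_code
    idx <- which(sel, arr.ind = TRUE)
    if (nrow(idx)) bcen[lv, ] <- colMeans(voxel_to_world(instances, idx))
  }

  # order caudal -> cranial for the spline
  ord <- order(-level_index(rownames(bcen)))
  cen_cc <- bcen[ord, , drop = FALSE]
  sp <- centroid_spline(cen_cc)

  geoms <- list()
  for (i in seq_len(nrow(cen_cc))) {
    lv <- rownames(cen_cc)[i]
    geoms[[lv]] <- extract_landmarks(subregions, instances, lv,
                                     superior_axis = sp$tangent(sp$t[i]))
  }

  joints <- list()
  lumbar_joints <- data.frame(
    name = c("T12/L1", "L1/L2", "L2/L3", "L3/L4", "L4/L5", "L5/S1"),
    sup = c("T12", "L1", "L2", "L3", "L4", "L5"),
    inf = c("L1", "L2", "L3", "L4", "L5", "sacrum"))
  for (k in seq_len(nrow(lumbar_joints))) {
    inf <- geoms[[lumbar_joints$inf[k]]]
    sup <- geoms[[lumbar_joints$sup[k]]]
    row_inf <- which(rownames(cen_cc) == lumbar_joints$inf[k])
    off <- sqrt(sum((inf$endplate_superior_center - inf$body_centroid)^2))
    joints[[lumbar_joints$name[k]]] <- list(
      name = lumbar_joints$name[k],
      origin = joint_center(inf, sup),
      R = joint_orientation(cen_cc, row_inf, endplate_offset_mm = off))
  }

  list(geometries = geoms, joints = joints,
       alignment = measure_alignment(geoms),
       transform = transform, centroids = cen)
}

#' Write extracted geometry to JSON
#'
#' @param geometry result of [extract_geometry()]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_geometry_json <- function(geometry, path) {
  enc <- list(
    alignment = geometry$alignment,
    levels = lapply(geometry$geometries, function(g) list(
      centroid = g$centroid,
      endplate_superior_center = g$endplate_superior_center,
      endplate_inferior_center = g$endplate_inferior_center,
      landmarks = g$landmarks)),
    joints = lapply(geometry$joints, function(j) list(
      origin = j$origin, rotation = as.vector(j$R))))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
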