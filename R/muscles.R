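# Trunk muscle architecture: nine groups discretized as point-to-point
# actuators.  Muscles acting locally on the lumbar spine attach to named
# vertebral landmarks; globally acting abdominal muscles and the
# ribcage-attached fascicles of the long erector spinae run between generic
# pelvis and ribcage points and are lumped to one actuator per side.  The
# default table yields 103 actuators: 49 per side plus 5 midline
# interspinales.

MUSCLE_GROUPS <- c("RA", "IO", "EO", "PM", "QL", "MF", "LL", "IL", "IS")

body_of_level <- function(level) {
  if (grepl("^T", level)) "thorax"
  else if (level == "sacrum") "sacrum"
  else level
}

#' Generic pelvis, ribcage and head-neck attachment points
#'
#' Points not captured by the vertebral segmentation (iliac crest, pubis,
#' trochanter, ribs, shoulders, head-neck centre of mass), placed relative
#' to the extracted spine geometry and scaled with stature.
#'
#' @param geometries named list of `vertebra_geometry`
#' @param scale geometric scale factor (1 = reference stature)
#' @return named list of `list(body =, point =)` entries
#' @export
generic_points <- function(geometries, scale = 1) {
  s0 <- geometries$sacrum$body_centroid
  lm <- function(level, name) geometries[[level]]$landmarks[[name]]
  ct <- function(level) geometries[[level]]$centroid
  pel <- function(off) list(body = "sacrum", point = s0 + off * scale)
  tho <- function(base, off) list(body = "thorax", point = base + off * scale)
  pts <- list(
    pubic = pel(c(90, -140, 0)),
    xiphoid = tho(lm("T10", "body_ant_center"), c(60, 0, 0)),
    chest = tho(lm("T8", "body_ant_center"), c(90, 0, 0)),
    head_neck_com = tho(ct("T1"), c(0, 120, 0)),
    sacrum_sup = list(body = "sacrum",
                      point = geometries$sacrum$endplate_superior_center))
  for (sd in c("left", "right")) {
    zs <- if (sd == "left") 1 else -1
    tv <- paste0("transverse_", sd, "_lateral")
    side <- list(
      iliac_crest_post = pel(c(-50, -30, zs * 55)),
      iliac_crest_lat = pel(c(10, -50, zs * 120)),
      iliac_post_lat = pel(c(-40, -40, zs * 85)),
      iliac_ant = pel(c(60, -60, zs * 100)),
      # effective straight-line surrogate for the psoas path over the
      # pelvic brim: anterior of the hip, so the lumbar flexion arm of the
      # fascicles is preserved without via points
      trochanter = pel(c(40, -180, zs * 90)),
      sacrum_mf1 = pel(c(-35, 10, zs * 15)),
      sacrum_mf2 = pel(c(-30, -10, zs * 20)),
      rib_lower_lat = tho(ct("T11"), c(40, 0, zs * 110)),
      rib_lower_med = tho(lm("T11", "body_ant_center"), c(30, 0, zs * 60)),
      rib12_post = tho(lm("T12", tv), c(-10, 0, zs * 15)),
      rib_post_up = tho(ct("T6"), c(-40, 0, zs * 60)),
      rib_lower_post = tho(ct("T10"), c(-30, 0, zs * 95)),
      shoulder = tho(ct("T2"), c(20, 10, zs * 170)))
    names(side) <- paste0(names(side), "_", sd)
    pts <- c(pts, side)
  }
  pts
}

#' Default muscle fascicle table
#'
#' Reconstructy of the nine-group architecture: rectus abdominis (RA),
#' internal/external obliques (IO, EO) and the ribcage-attached fascicles
#' of longissimus (LL), iliocostalis (IL) and quadratus lumborum (QL) as
#' one actuator per side; detailed lumbar fascicles for psoas major (PM),
#' QL, multifidus (MF), LL and IL bound to vertebral landmarks; and five
#' midline interspinales (IS).  Thoracic MF and IS fascicles carry a PCSA
#' of 1 cm^2.
#'
#' @param geometries named list of `vertebra_geometry`
#' @param generic output of [generic_points()]
#' @return data frame: group, side, origin/insertion body, point (x3),
#'   name, pcsa_cm2
#' @export
default_muscle_table <- function(geometries, generic = NULL) {
  if (is.null(generic)) generic <- generic_points(geometries)
  rows <- list()
  add <- function(group, side, o_name, o_body, o_pt, i_name, i_body, i_pt,
                  pcsa) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, side = side,
      origin_name = o_name, origin_body = o_body,
      ox = o_pt[1], oy = o_pt[2], oz = o_pt[3],
      insertion_name = i_name, insertion_body = i_body,
      ix = i_pt[1], iy = i_pt[2], iz = i_pt[3],
      pcsa_cm2 = pcsa, stringsAsFactors = FALSE)
  }
  gp <- function(name) generic[[name]]
  lmk <- function(level, name) {
    p <- geometries[[level]]$landmarks[[name]]
    if (is.null(p)) stop("muscle assembly: unresolvable landmark '", name,
                         "' at level ", level)
    p
  }
  add_g <- function(group, side, o, i, pcsa) {
    add(group, side, o, gp(o)$body, gp(o)$point, i, gp(i)$body, gp(i)$point,
        pcsa)
  }
  for (sd in c("left", "right")) {
    sfx <- paste0("_", sd)
    tv <- paste0("transverse_", sd, "_lateral")
    blat <- paste0("body_", sd, "_lateral")
    # global abdominals: one actuator per side
    add_g("RA", sd, "pubic", "xiphoid", 6.0)
    add_g("EO", sd, paste0("rib_lower_lat", sfx), paste0("iliac_ant", sfx),
          12.0)
    add_g("IO", sd, paste0("iliac_crest_lat", sfx),
          paste0("rib_lower_med", sfx), 10.0)
    # psoas major: anterolateral vertebral bodies and transverse processes
    # L1-L5 + T12; the anterolateral body origin preserves the muscle's
    # weak flexion arm at the upper lumbar joints
    for (lv in paste0("L", 1:5)) {
      alat <- 0.75 * lmk(lv, "body_ant_center") + 0.25 * lmk(lv, blat)
      add("PM", sd, paste0(lv, ".body_anterolateral_", sd), lv, alat,
          paste0("trochanter", sfx), "sacrum", gp(paste0("trochanter", sfx))$point,
          2.2)
      add("PM", sd, paste0(lv, ".", tv), lv, lmk(lv, tv),
          paste0("trochanter", sfx), "sacrum", gp(paste0("trochanter", sfx))$point,
          1.5)
    }
    add("PM", sd, paste0("T12.body_anterolateral_", sd), "thorax",
        0.5 * (lmk("T12", "body_ant_center") + lmk("T12", blat)),
        paste0("trochanter", sfx), "sacrum",
        gp(paste0("trochanter", sfx))$point, 1.2)
    # quadratus lumborum: L1-L4 transverse processes + 12th rib
    for (lv in paste0("L", 1:4))
      add("QL", sd, paste0(lv, ".", tv), lv, lmk(lv, tv),
          paste0("iliac_crest_lat", sfx), "sacrum",
          gp(paste0("iliac_crest_lat", sfx))$point, 0.8)
    add_g("QL", sd, paste0("rib12_post", sfx),
          paste0("iliac_crest_post", sfx), 1.9)
    # longissimus: lumbar fascicles L1-L5 + pars thoracis
    for (lv in paste0("L", 1:5))
      add("LL", sd, paste0(lv, ".", tv), lv, lmk(lv, tv),
          paste0("iliac_crest_post", sfx), "sacrum",
          gp(paste0("iliac_crest_post", sfx))$point, 2.1)
    add_g("LL", sd, paste0("rib_post_up", sfx),
          paste0("iliac_crest_post", sfx), 11.0)
    # iliocostalis: lumbar fascicles L1-L3 + ribcage part
    for (lv in paste0("L", 1:3))
      add("IL", sd, paste0(lv, ".", tv), lv, lmk(lv, tv),
          paste0("iliac_post_lat", sfx), "sacrum",
          gp(paste0("iliac_post_lat", sfx))$point, 1.8)
    add_g("IL", sd, paste0("rib_lower_post", sfx),
          paste0("iliac_post_lat", sfx), 10.0)
    # multifidus: spinous process origins, caudal insertions 2-4 levels down
    mf_targets <- list(
      L1 = c("tv.L3", "tv.L4", "tv.L5", "sacrum_mf1"),
      L2 = c("tv.L4", "tv.L5", "sacrum_mf1"),
      L3 = c("tv.L5", "sacrum_mf1", "sacrum_mf2", "iliac_crest_post"),
      L4 = c("sacrum_mf1", "sacrum_mf2", "iliac_crest_post"),
      L5 = c("sacrum_mf1", "sacrum_mf2", "iliac_crest_post"))
    for (lv in names(mf_targets)) {
      for (tg in mf_targets[[lv]]) {
        if (startsWith(tg, "tv.")) {
          tlv <- sub("tv\\.", "", tg)
          add("MF", sd, paste0(lv, ".spinous_inferior"), lv,
              lmk(lv, "spinous_inferior"), paste0(tlv, ".", tv), tlv,
              lmk(tlv, tv), 0.8)
        } else {
          add("MF", sd, paste0(lv, ".spinous_inferior"), lv,
              lmk(lv, "spinous_inferior"), paste0(tg, sfx), "sacrum",
              gp(paste0(tg, sfx))$point, 0.8)
        }
      }
    }
    # thoracic multifidus fascicles (PCSA fixed at 1 cm^2 each).  With the
    # thoracic spine fused to one rigid body, every fascicle descending
    # from a thoracic spinous process onto L1 spans T12/L1 alone; their
    # posterior lines of action decouple that joint's sagittal balance
    # from the upper lumbar levels.
    add("MF", sd, "T12.spinous_inferior", "thorax",
        lmk("T12", "spinous_inferior"), "L1.spinous_superior", "L1",
        lmk("L1", "spinous_superior"), 1.0)
    add("MF", sd, "T11.spinous_inferior", "thorax",
        lmk("T11", "spinous_inferior"), "L1.spinous_superior", "L1",
        lmk("L1", "spinous_superior"), 1.0)
    add("MF", sd, "T12.spinous_inferior.b", "thorax",
        lmk("T12", "spinous_inferior"), paste0("L1.", tv), "L1",
        lmk("L1", tv), 1.0)
  }
  # midline interspinales L1/L2 .. L5/S1 (PCSA 1 cm^2)
  pairs <- rbind(c("L1", "L2"), c("L2", "L3"), c("L3", "L4"),
                 c("L4", "L5"), c("L5", "sacrum"))
  for (k in seq_len(nrow(pairs))) {
    up <- pairs[k, 1]; lo <- pairs[k, 2]
    add("IS", "mid", paste0(up, ".spinous_inferior"), up,
        lmk(up, "spinous_inferior"), paste0(lo, ".spinous_superior"), lo,
        lmk(lo, "spinous_superior"), 1.0)
  }
  do.call(rbind, rows)
}

#' Build muscle fascicles from a table, merging shared attachments
#'
#' Fascicles of the same group and side attaching to the same origin and
#' insertion subregion points are combined into one actuator whose PCSA is
#' the sum of the merged fascicles.
#'
#' @param geometries named list of `vertebra_geometry`
#' @param generic output of [generic_points()] (computed if `NULL`)
#' @param table fascicle table (default [default_muscle_table()])
#' @return data frame of actuators (class `muscle_set`)
#' @export
build_muscles <- function(geometries, generic = NULL, table = NULL) {
  if (is.null(generic)) generic <- generic_points(geometries)
  if (is.null(table)) table <- default_muscle_table(geometries, generic)
  need <- c("group", "side", "origin_name", "origin_body", "ox", "oy", "oz",
            "insertion_name", "insertion_body", "ix", "iy", "iz",
            "pcsa_cm2")
  if (!all(need %in% names(table)))
    stop("muscle table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (any(table$pcsa_cm2 <= 0)) stop("PCSA must be positive")
  key <- with(table, paste(group, side, origin_name, insertion_name))
  merged <- table[!duplicated(key), ]
  merged$pcsa_cm2 <- as.numeric(tapply(table$pcsa_cm2, key, sum)[
    with(merged, paste(group, side, origin_name, insertion_name))])
  deg <- with(merged, (ox - ix)^2 + (oy - iy)^2 + (oz - iz)^2) < 1e-9
  if (any(deg)) stop("zero-length fascicle(s): ",
                     paste(merged$origin_name[deg], collapse = ", "))
  rownames(merged) <- NULL
  class(merged) <- c("muscle_set", class(merged))
  merged
}
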