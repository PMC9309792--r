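# Shared fixtures, built once per test run and memoized.  The full
# synthetic spine takes a few seconds to generate and extract, so the
# heavier tests share one lordotic build (the default study alignment) and
# one straight build.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

fx_spine <- function(preset = "lordotic", ...) {
  memo(paste0("spine_", preset), {
    generate_spine_volume(spine_preset(preset, ...))
  })
}

fx_geometry <- function(preset = "lordotic") {
  memo(paste0("geom_", preset), {
    s <- fx_spine(preset)
    extract_geometry(s$instances, s$subregions)
  })
}

fx_model <- function(preset = "lordotic") {
  memo(paste0("model_", preset), {
    p <- spine_preset(preset)
    s <- fx_spine(preset)
    tis <- generate_tissue_volume(p, s$instances)
    g <- fx_geometry(preset)
    tl <- classify_tissues(transform_volume(tis, g$transform),
                           instances = transform_volume(s$instances,
                                                        g$transform))
    seg <- assign_to_levels(tl, g$geometries)
    list(model = assemble_model(g, seg, s$instances), segments = seg,
         geometry = g, tissue = tis, spine = s, params = p)
  })
}

fx_neutral <- function(preset = "lordotic") {
  memo(paste0("neutral_", preset), neutral_posture(fx_model(preset)$model))
}

fx_battery <- function(preset = "lordotic",
                       cases = c("standing", "flexion_10", "flexion_30",
                                 "standing_20kg_20cm_chest")) {
  memo(paste0("battery_", preset, "_", paste(cases, collapse = "+")), {
    simulate_load_cases(fx_model(preset)$model,
                        default_load_cases()[cases],
                        neutral = fx_neutral(preset))
  })
}

# A hand-built minimal chain model with unit geometry: six joints stacked
# 30 mm apart on the vertical axis with identity frames, massless bodies
# (masses settable), no ligaments, zero-stiffness discs and a muscle table
# supplied by the caller.  Serves as an analytic oracle for the statics
# code, independent of the volumetric pipeline.
make_stick_model <- function(masses = c(thorax = 0),
                             thorax_com = c(0, 200, 0),
                             muscles = NULL,
                             disc_stiffness = 0) {
  joint_names <- c("L5/S1", "L4/L5", "L3/L4", "L2/L3", "L1/L2", "T12/L1")
  parents <- c("sacrum", "L5", "L4", "L3", "L2", "L1")
  children <- c("L5", "L4", "L3", "L2", "L1", "thorax")
  joints <- list()
  for (k in seq_along(joint_names)) {
    joints[[joint_names[k]]] <- list(
      name = joint_names[k], origin = c(0, 30 * k, 0),
      R = diag(3) |> `colnames<-`(c("anterior", "superior", "lateral")),
      parent = parents[k], child = children[k])
  }
  bodies <- list()
  for (bn in c("sacrum", paste0("L", 5:1), "thorax", "arm_left",
               "arm_right")) {
    com <- switch(bn, thorax = thorax_com, c(0, 15 + 30 * 5, 0))
    bodies[[bn]] <- list(name = bn,
                         mass_kg = if (bn %in% names(masses))
                           masses[[bn]] else 0,
                         com = com, levels = character(0))
  }
  if (is.null(muscles)) {
    muscles <- data.frame(
      group = "LL", side = "left", origin_name = "o", origin_body = "thorax",
      ox = -50, oy = 200, oz = 0,
      insertion_name = "i", insertion_body = "sacrum",
      ix = -50, iy = 0, iz = 0, pcsa_cm2 = 10)
  }
  discs <- lapply(joint_names, function(jn)
    disc_element(jn, c(frontal = 0, axial = 0, sagittal = 0),
                 c(frontal = disc_stiffness, axial = disc_stiffness,
                   sagittal = disc_stiffness)))
  names(discs) <- joint_names
  structure(list(bodies = bodies, joints = joints, ligaments = list(),
                 discs = discs, muscles = muscles,
                 points = list(), external = list(),
                 generic = list(geometry_scale = 1),
                 provenance = list()),
            class = "spine_model")
}
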