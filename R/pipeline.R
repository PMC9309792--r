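# End-to-end pipeline driver: synthetic generation or volume input ->
# geometry extraction -> tissue mass partition -> model assembly ->
# neutral-posture optimization -> load-case battery -> reports.

#' Pipeline configuration
#'
#' @param preset synthetic preset name ("straight", "lordotic",
#'   "scoliotic"), or `NULL` when volume paths are given
#' @param instances,subregions,tissue NIfTI paths for pre-existing volumes
#'   (all three required together; ignored when `preset` is set)
#' @param out_dir output directory
#' @param seed integer seed recorded in and used by the run
#' @param stature_m body height for generic-segment scaling
#' @param load_cases "default", or a YAML path for [read_load_cases()]
#' @param sigma_max_mpa maximal muscle stress sequence (primary, fallback)
#' @param tol moment-equilibrium tolerance, N*m
#' @param params optional [spine_params()] overriding `preset`
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(preset = "lordotic", instances = NULL,
                            subregions = NULL, tissue = NULL,
                            out_dir = "spineload_out", seed = 1L,
                            stature_m = 1.74, load_cases = "default",
                            sigma_max_mpa = c(0.6, 1.0), tol = 0.1,
                            params = NULL) {
  cfg <- list(preset = preset, instances = instances,
              subregions = subregions, tissue = tissue,
              out_dir = out_dir, seed = as.integer(seed),
              stature_m = stature_m, load_cases = load_cases,
              sigma_max_mpa = sigma_max_mpa, tol = tol, params = params)
  if (is.null(cfg$preset) && is.null(cfg$params)) {
    for (f in c("instances", "subregions", "tissue"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("pipeline config error: missing input volume file for '", f,
             "': ", if (is.null(cfg[[f]])) "(not set)" else cfg[[f]])
  }
  if (is.character(cfg$load_cases) && cfg$load_cases != "default" &&
      !file.exists(cfg$load_cases))
    stop("pipeline config error: load-case file not found: ",
         cfg$load_cases)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  # hash the scientific configuration only; the output directory is run
  # plumbing and must not break reproducibility comparisons
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  enc <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE)
  # small stable polynomial hash; avoids external digest dependencies
  h <- 0
  for (b in utf8ToInt(as.character(enc))) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_csv_plain <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline
#'
#' Stages: synthesize or load volumes; extract geometry and alignment;
#' classify tissues and partition masses; assemble the model; optimize the
#' neutral standing posture; simulate the load-case battery; write the
#' model JSON, result CSVs (fascicle forces, joint reactions, normalized
#' compression, ligament utilization), the alignment report and a run log
#' with the config hash, seed and stage timings.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, the list of in-memory results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("spineload pipeline run"),
                 paste0("seed: ", config$seed),
                 paste0("config_hash: ", config_hash(config)))
  t_all <- Sys.time()
  stamp <- function(stage, t0)
    log_lines <<- c(log_lines, sprintf("%-22s %.2f s", stage,
                                       as.numeric(Sys.time() - t0,
                                                  units = "secs")))
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stamp(stage, t0)
    out
  }

  vols <- run_stage("volumes", {
    if (!is.null(config$params) || !is.null(config$preset)) {
      p <- if (!is.null(config$params)) config$params
           else spine_preset(config$preset, seed = config$seed)
      sp <- generate_spine_volume(p)
      tis <- generate_tissue_volume(p, sp$instances)
      write_synthetic_spine(sp, file.path(config$out_dir, "volumes"))
      write_labeled_volume(tis, file.path(config$out_dir, "volumes",
                                          "tissue.nii.gz"))
      list(instances = sp$instances, subregions = sp$subregions,
           tissue = tis)
    } else {
      list(instances = read_labeled_volume(config$instances),
           subregions = read_labeled_volume(config$subregions),
           tissue = read_labeled_volume(config$tissue))
    }
  })

  geo <- run_stage("geometry", {
    g <- extract_geometry(vols$instances, vols$subregions)
    write_geometry_json(g, file.path(config$out_dir, "geometry.json"))
    jsonlite::write_json(c(g$alignment, seed = config$seed,
                           config_hash = config_hash(config)),
                         file.path(config$out_dir, "alignment.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    g
  })

  seg <- run_stage("mass", {
    tl <- classify_tissues(transform_volume(vols$tissue, geo$transform),
                           instances = transform_volume(vols$instances,
                                                        geo$transform))
    s <- assign_to_levels(tl, geo$geometries)
    write_csv_plain(s, file.path(config$out_dir, "segments.csv"))
    s
  })

  model <- run_stage("assemble", {
    m <- assemble_model(geo, seg, vols$instances,
                        stature_m = config$stature_m)
    m$provenance$seed <- config$seed
    m$provenance$config_hash <- config_hash(config)
    model_to_json(m, file.path(config$out_dir, "model.json"))
    m
  })

  neutral <- run_stage("neutral_posture", neutral_posture(model))
  log_lines <- c(log_lines,
                 sprintf("neutral max |M_z|: %.4g N*m",
                         attr(neutral, "max_abs_mz_nm")))

  cases <- if (identical(config$load_cases, "default")) default_load_cases()
           else if (is.character(config$load_cases))
             read_load_cases(config$load_cases)
           else config$load_cases

  res <- run_stage("simulate", {
    r <- simulate_load_cases(model, cases, neutral = neutral,
                             sigma_max_mpa = config$sigma_max_mpa,
                             tol = config$tol)
    forces <- do.call(rbind, lapply(names(r$solutions), function(nm)
      data.frame(case = nm, fascicle = seq_along(r$solutions[[nm]]$forces),
                 group = model$muscles$group, side = model$muscles$side,
                 origin = model$muscles$origin_name,
                 force_n = as.numeric(r$solutions[[nm]]$forces),
                 sigma_max_mpa = r$solutions[[nm]]$sigma_max_mpa)))
    reacts <- do.call(rbind, lapply(names(r$reactions), function(nm)
      cbind(case = nm, r$reactions[[nm]])))
    util <- do.call(rbind, lapply(names(r$utilization), function(nm)
      cbind(case = nm, r$utilization[[nm]])))
    hdr <- sprintf("# seed=%d config_hash=%s", config$seed,
                   config_hash(config))
    for (fn in c("forces", "reactions", "normalized", "utilization")) {
      df <- switch(fn, forces = forces, reactions = reacts,
                   normalized = r$normalized, utilization = util)
      path <- file.path(config$out_dir, paste0(fn, ".csv"))
      writeLines(hdr, path)
      suppressWarnings(utils::write.table(
        format(df, digits = 12, trim = TRUE, scientific = FALSE), path,
        sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
    }
    r
  })

  log_lines <- c(log_lines,
                 sprintf("total                  %.2f s",
                         as.numeric(Sys.time() - t_all, units = "secs")))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(volumes = vols, geometry = geo, segments = seg,
                 model = model, neutral = neutral, results = res,
                 config = config))
}
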