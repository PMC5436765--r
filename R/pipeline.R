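# End-to-end pipeline: simulate -> sample -> metrics -> calibrate.

pipeline_defaults <- function() {
  list(
    scenario = list(days = 3, tolerances = "standard", output_dt = 1,
                    kindle_start_clock = "21:12", kindle_day = 2,
                    kindle_duration_min = 50, pulse_intensity = 5e-8,
                    sham_multiplier = 1.1765),
    forcing = list(d1 = 0.2662, d2 = 2.5),
    sampling = list(variant = "B", cv = 0.041, missingness_prob = 0,
                    n_control = 3, n_sham = 4, n_kindled = 4),
    calibration = list(enabled = TRUE,
                       intensity_grid = c(1e-8, 2e-8, 5e-8, 1e-7, 2e-7),
                       multiplier_bounds = c(1, 1.4),
                       multiplier_grid_n = 33,
                       fit_multiplier = FALSE),
    analysis = list(discard_days = 1),
    seed = 1)
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults and merges the supplied sections.
#' Unknown section or key names are rejected outright, so a typo fails
#' fast instead of silently running with a default.
#'
#' @param ... Named sections (`scenario`, `forcing`, `sampling`,
#'   `calibration`, `analysis`) given as lists, and/or a top-level
#'   `seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  user <- list(...)
  if (length(user) && is.null(names(user)))
    stop("pipeline_config() arguments must be named")
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stop("unknown config section: ", section)
    if (section == "seed") { cfg$seed <- user$seed; next }
    if (!is.list(user[[section]]))
      stop("section '", section, "' must be a list")
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown key '", key, "' in section '", section, "'")
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path File ending in .json, .yaml or .yml; its sections are
#'   validated by [pipeline_config()]. A stored run configuration must be
#'   complete: by default every section has to be present in the file, and
#'   a missing one is an error naming it.
#' @param require_all_sections Check that every section is present
#'   (default TRUE).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, require_all_sections = TRUE) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = , yml = yaml::read_yaml(path),
                stop("unsupported config format: .", ext))
  if (require_all_sections) {
    missing <- setdiff(names(pipeline_defaults()), names(raw))
    if (length(missing))
      stop("config is missing section(s): ",
           paste(missing, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

pipeline_stage <- function(name, manifest, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = paste0("stage '", name, "' failed: ",
                                         conditionMessage(e)),
                        call = sys.call(-1), stage = name,
                        manifest = manifest)))
  })
}

#' Run the full synthetic pipeline
#'
#' Simulates the control, sham and kindled scenarios, draws a synthetic
#' cohort, computes oscillation metrics per scenario, optionally
#' calibrates the pulse intensity (and stress multiplier) back from the
#' cohort, and writes every artefact plus a manifest with content hashes
#' and the resolved configuration into `out_dir`. All randomness flows
#' from `config$seed`, so a rerun writes bit-identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest: data.frame with `file` and `md5`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit <- function(path) manifest <<- c(manifest, path)
  sc <- config$scenario
  forcing <- forcing_params(d1 = config$forcing$d1, d2 = config$forcing$d2)
  t_end <- sc$days * 1440
  ks <- clock_to_minutes(sc$kindle_start_clock, day = sc$kindle_day)

  trajs <- pipeline_stage("simulate", manifest, {
    base <- function(cond, mult, sched = NULL)
      simulate_scenario(scenario_config(
        cond, k2_multiplier = mult, schedule = sched, t_end = t_end,
        tolerances = sc$tolerances, forcing = forcing,
        output_dt = sc$output_dt))
    out <- list(
      control = base("control", 1),
      sham = base("sham", sc$sham_multiplier),
      kindled = base("custom", sc$sham_multiplier,
                     kindling_schedule(ks,
                                       duration_min = sc$kindle_duration_min,
                                       intensity = sc$pulse_intensity)))
    for (nm in names(out))
      emit(write_trajectory_csv(out[[nm]],
                                file.path(out_dir,
                                          paste0("trajectory_", nm,
                                                 ".csv"))))
    out
  })

  cohort <- pipeline_stage("sample", manifest, {
    sp <- config$sampling
    ch <- make_cohort(trajs,
                      n_per_group = c(control = sp$n_control,
                                      sham = sp$n_sham,
                                      kindled = sp$n_kindled),
                      schedule = make_schedule(sp$variant,
                                               kindle_start = ks,
                                               kindle_duration_min =
                                                 sc$kindle_duration_min),
                      cv = sp$cv, missingness_prob = sp$missingness_prob,
                      seed = config$seed)
    emit(write_cohort_csv(ch, file.path(out_dir, "cohort.csv")))
    ch
  })

  metrics <- pipeline_stage("metrics", manifest, {
    w0 <- config$analysis$discard_days * 1440
    m <- lapply(trajs, function(tr)
      unclass(detect_ultradian(tr, window = c(w0, t_end))))
    m <- lapply(m, function(x) {
      x$daily_mean_M <- as.list(x$daily_mean_M)
      x$largest_amplitude_bounds_M <-
        as.list(x$largest_amplitude_bounds_M)
      x
    })
    path <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    emit(path)
    m
  })

  calib <- NULL
  if (isTRUE(config$calibration$enabled)) {
    calib <- pipeline_stage("calibrate", manifest, {
      cc <- config$calibration
      kindled <- Filter(function(s) attr(s, "group") == "kindled", cohort)
      fit <- fit_pulse_intensity(
        kindled, cc$intensity_grid,
        scenario_for_intensity = function(x)
          lhk_scenario(x, kindle_start = ks,
                       duration_min = sc$kindle_duration_min,
                       k2_multiplier = sc$sham_multiplier,
                       t_end = t_end, tolerances = sc$tolerances))
      res <- list(pulse_intensity = list(estimate = fit$estimate,
                                         objective = fit$objective,
                                         trace = fit$trace))
      if (isTRUE(cc$fit_multiplier)) {
        sham <- Filter(function(s) attr(s, "group") == "sham", cohort)
        fm <- fit_stress_multiplier(
          sham, bounds = cc$multiplier_bounds,
          n_grid = cc$multiplier_grid_n,
          scenario_for_multiplier = function(m)
            scenario_config("custom", k2_multiplier = m, t_end = t_end,
                            tolerances = sc$tolerances, forcing = forcing))
        res$k2_multiplier <- list(estimate = fm$estimate,
                                  objective = fm$objective,
                                  trace = fm$trace)
      }
      anova <- group_comparison(cohort)
      res$anova <- list(F = anova$F, df1 = anova$df1, df2 = anova$df2,
                        p_value = anova$p_value)
      path <- file.path(out_dir, "calibration.json")
      jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
      emit(path)
      res
    })
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  emit(cfg_path)
  man <- data.frame(file = basename(manifest),
                    md5 = unname(tools::md5sum(manifest)))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
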