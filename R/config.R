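#' Default run configuration
#'
#' The configuration tree consumed by the `cmd_*` entry points and the
#' command-line front end (`inst/cli/wellcolor`). Keys: `grid` (`rows`,
#' `cols`, `pitch_px`, `first_center_px`), `roi.radius_px`, `mask`
#' (`k_mad`, `glare_min`, `reject_fraction`), `analysis` (`channel`,
#' `r2_min`, `backcalc_bias_max`), `study` (`preset` or `levels` +
#' `n_runs`), `seed`.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    grid = list(rows = 1L, cols = 8L, pitch_px = 70,
                first_center_px = c(60, 60)),
    roi = list(radius_px = 25),
    mask = list(k_mad = 3.5, glare_min = 250, reject_fraction = 0.30),
    analysis = list(channel = "auto", r2_min = 0.98,
                    backcalc_bias_max = 15),
    study = list(preset = NULL, levels = NULL, n_runs = NULL),
    seed = NULL
  )
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ",
           paste(c(path, nm), collapse = "."), call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    } else if (is.null(override[[nm]])) {
      base[nm] <- list(NULL)            # keep the key, don't delete it
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_run_config()] (unknown keys
#' are rejected), and validates threshold ranges. `overrides` (e.g. from
#' command-line flags) take precedence over the file, which takes
#' precedence over the defaults.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  a <- cfg$analysis
  if (!is.null(a$channel) && a$channel != "auto") {
    match.arg(a$channel, setdiff(dic_channels(), "hue"))
  }
  stopifnot(a$r2_min > 0, a$r2_min <= 1,
            a$backcalc_bias_max > 0,
            cfg$mask$reject_fraction >= 0, cfg$mask$reject_fraction <= 1,
            cfg$mask$k_mad > 0,
            cfg$mask$glare_min > 0, cfg$mask$glare_min <= 255,
            cfg$roi$radius_px > 0, cfg$grid$pitch_px > 0)
  if (!is.null(cfg$seed)) {
    stopifnot(is.numeric(cfg$seed), cfg$seed == as.integer(cfg$seed))
  }
  cfg
}

config_layout <- function(cfg) {
  well_layout(n_rows = cfg$grid$rows, n_cols = cfg$grid$cols,
              pitch_px = cfg$grid$pitch_px,
              first_center_px = as.numeric(cfg$grid$first_center_px),
              roi_radius_px = cfg$roi$radius_px)
}

#' Command entry point: simulate a study
#'
#' Generates a validation study per the configuration's `study` block:
#' either `preset: "table3"` (7 runs at the six characterised QC levels)
#' or explicit `levels` and `n_runs`. Requires `seed` in the
#' configuration; identical configuration and seed reproduce the run
#' directory bit for bit.
#'
#' @param config Configuration list from [load_run_config()].
#' @param out_dir Output directory.
#' @param model A [response_model()]; defaults to the characterised urea
#'   response.
#' @return The study index tibble, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, model = response_model()) {
  if (is.null(config$seed)) {
    stop("validation error: simulation requires `seed` in the configuration",
         call. = FALSE)
  }
  study <- config$study
  if (identical(study$preset, "table3")) {
    levels <- table3_qc_levels()
    n_runs <- study$n_runs %||% 7L
  } else {
    if (is.null(study$levels) || is.null(study$n_runs)) {
      stop("study configuration needs `preset: table3` or explicit ",
           "`levels` and `n_runs`", call. = FALSE)
    }
    levels <- as.numeric(study$levels)
    n_runs <- study$n_runs
  }
  idx <- simulate_validation_study(model, levels = levels, n_runs = n_runs,
                                   dir = out_dir, seed = config$seed)
  message("simulated study with ", nrow(idx), " run(s) in ", out_dir,
          " (index: ", file.path(out_dir, "study.csv"), ")")
  invisible(idx)
}

#' Command entry point: analyse one photo
#'
#' Runs [analyze_plate()] and writes `observations.csv`,
#' `calibration.json`, `channel_comparison.csv` and `results.csv` into
#' `out_dir`.
#'
#' @param image,plate_map,layout Paths (image PNG/TIFF, plate-map CSV,
#'   layout YAML; layout defaults to the configuration's grid).
#' @param config Configuration list.
#' @param out_dir Output directory.
#' @return The `plate_analysis`, invisibly.
#' @export
cmd_analyze <- function(image, plate_map, config, out_dir, layout = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lay <- if (is.null(layout)) config_layout(config) else layout
  an <- analyze_plate(
    image, plate_map, lay,
    channel = config$analysis$channel,
    r2_min = config$analysis$r2_min,
    backcalc_bias_max = config$analysis$backcalc_bias_max,
    k_mad = config$mask$k_mad,
    glare_brightness_min = config$mask$glare_min,
    reject_fraction = config$mask$reject_fraction)
  write_observations(an$observations, file.path(out_dir, "observations.csv"))
  all_curves <- purrr::flatten(an$curves)
  write_calibration_json(all_curves, file.path(out_dir, "calibration.json"))
  write_channel_comparison(all_curves,
                           file.path(out_dir, "channel_comparison.csv"))
  readr::write_csv(an$results, file.path(out_dir, "results.csv"))
  invisible(an)
}

#' Command entry point: validate a study
#'
#' Analyses every run of a study directory and writes the validation
#' report (`validation.json` and the per-level `validation.csv`).
#'
#' @param study_dir Study directory (from [cmd_simulate()] or an
#'   equivalently laid-out set of real photographs).
#' @param config Configuration list.
#' @param out_dir Output directory (defaults to `study_dir`).
#' @return The study analysis list from [analyze_validation_study()],
#'   invisibly.
#' @export
cmd_validate <- function(study_dir, config, out_dir = study_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ch <- config$analysis$channel
  res <- analyze_validation_study(
    study_dir,
    channel = if (identical(ch, "auto")) "blue" else ch,
    r2_min = config$analysis$r2_min,
    backcalc_bias_max = config$analysis$backcalc_bias_max,
    k_mad = config$mask$k_mad,
    glare_brightness_min = config$mask$glare_min,
    reject_fraction = config$mask$reject_fraction)
  write_validation_json(res$report, file.path(out_dir, "validation.json"))
  write_validation_csv(res$report, file.path(out_dir, "validation.csv"))
  invisible(res)
}
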