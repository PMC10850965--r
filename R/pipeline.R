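#' Analyse one plate photograph end to end
#'
#' Runs well localisation, ROI extraction with artifact masking,
#' calibration on the photo's own standard wells, channel selection, and
#' quantification of every sample well: `qc` and `sample` wells are
#' back-calculated directly (replicate wells sharing matrix and nominal
#' concentration are averaged first); `spiked_sample` wells together with
#' the `reference_standard` wells of the same matrix are quantified by
#' modified standard addition.
#'
#' @param image A [plate_image] or a path to a PNG/TIFF file.
#' @param plate_map A plate-map tibble or CSV path.
#' @param layout A [well_layout] or a layout YAML path.
#' @param channel Analytical channel, or `"auto"` to pick by
#'   [select_channel()].
#' @param r2_min,backcalc_bias_max Calibration acceptance thresholds.
#' @param k_mad,glare_brightness_min,reject_fraction Masking parameters,
#'   see [read_plate()].
#' @return An object of class `plate_analysis`: `observations`, `curves`
#'   (one per fitted channel), `channel` (the one used), `results`
#'   (quantification tibble).
#' @export
analyze_plate <- function(image, plate_map, layout, channel = "auto",
                          r2_min = 0.98, backcalc_bias_max = 15,
                          k_mad = 3.5, glare_brightness_min = 250,
                          reject_fraction = 0.30) {
  if (is.character(image)) image <- read_plate_image(image)
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  if (is.character(layout)) layout <- read_layout_yaml(layout)
  if (!any(plate_map$role == "standard")) {
    stop("cannot calibrate: plate map contains no standard wells",
         call. = FALSE)
  }
  layout <- locate_wells(image, layout)
  obs <- read_plate(image, layout, plate_map, k_mad = k_mad,
                    glare_brightness_min = glare_brightness_min,
                    reject_fraction = reject_fraction)
  channels <- if (identical(channel, "auto")) {
    setdiff(dic_channels(), "hue")
  } else {
    match.arg(channel, setdiff(dic_channels(), "hue"))
  }
  curves_by_matrix <- obs |>
    dplyr::filter(.data$role == "standard", .data$valid) |>
    dplyr::pull(.data$matrix) |>
    unique() |>
    rlang::set_names() |>
    purrr::map(~ fit_calibration(obs, channels = channels, matrix = .x,
                                 r2_min = r2_min,
                                 backcalc_bias_max = backcalc_bias_max))
  results <- purrr::imap_dfr(curves_by_matrix, function(curves, mat) {
    if (!length(curves)) {
      stop("cannot calibrate matrix '", mat, "': no channel has a linear ",
           "range", call. = FALSE)
    }
    use_ch <- if (identical(channel, "auto")) {
      select_channel(curves, r2_min = r2_min)
    } else channel
    if (is.null(curves[[use_ch]])) {
      stop("requested channel '", use_ch, "' has no valid calibration in ",
           "matrix '", mat, "'", call. = FALSE)
    }
    curve <- curves[[use_ch]]
    sig_col <- channel_column(use_ch)
    mat_obs <- dplyr::filter(obs, .data$matrix == mat, .data$valid)

    direct_obs <- dplyr::filter(mat_obs, .data$role %in% c("qc", "sample"))
    direct <- if (nrow(direct_obs)) {
      direct_obs |>
        dplyr::group_by(.data$role, .data$nominal_conc) |>
        dplyr::group_map(function(grp, key) {
          id <- paste0(mat, ":", key$role,
                       if (!is.na(key$nominal_conc)) paste0("@", key$nominal_conc))
          quantify_direct(curve, grp[[sig_col]], sample_id = id) |>
            dplyr::mutate(matrix = mat, nominal_conc = key$nominal_conc)
        }) |>
        dplyr::bind_rows()
    } else NULL

    spiked <- dplyr::filter(mat_obs, .data$role == "spiked_sample")
    refs <- dplyr::filter(mat_obs, .data$role == "reference_standard")
    sa <- NULL
    if (nrow(spiked)) {
      if (!nrow(refs)) {
        stop("spiked samples present in matrix '", mat, "' but no ",
             "reference_standard well", call. = FALSE)
      }
      design <- standard_addition_design(
        additions = tibble::tibble(added_conc = spiked$added_conc,
                                   signal = spiked[[sig_col]]),
        ref_conc = unique(refs$nominal_conc)[1],
        ref_signal = refs[[sig_col]],
        channel = use_ch, matrix = mat,
        range_lo = curve$linear_range[1])
      sa <- quantify_standard_addition(
        design, linear_range = curve$linear_range, r2_min = r2_min,
        sample_id = paste0(mat, ":standard_addition")) |>
        dplyr::mutate(matrix = mat, nominal_conc = NA_real_)
    }
    dplyr::bind_rows(direct, sa)
  })
  used_channel <- if (identical(channel, "auto")) {
    unique(results$channel) %||% channel
  } else channel
  structure(list(observations = obs, curves = curves_by_matrix,
                 channel = used_channel, results = results,
                 layout = layout),
            class = "plate_analysis")
}

#' @export
print.plate_analysis <- function(x, ...) {
  cat(sprintf("<plate_analysis> %d wells (%d valid), channel(s): %s\n",
              nrow(x$observations), sum(x$observations$valid),
              paste(unique(x$channel), collapse = ", ")))
  print(x$results)
  invisible(x)
}

#' Analyse a simulated or real validation study directory
#'
#' Reads the `study.csv` index written by [simulate_validation_study()]
#' (or an equivalently organised set of real photos), analyses each run
#' with its own in-photo calibration, and assembles the validation report
#' over the QC estimates.
#'
#' @param study_dir Directory containing `study.csv`, images, plate maps
#'   and `layout.yaml`.
#' @param channel Analytical channel for quantification (default blue,
#'   the channel whose concentration response this assay characterises
#'   most directly; `"auto"` selects per run).
#' @param ... Passed to [analyze_plate()].
#' @return A list: `report` (a `validation_report`), `results` (per-run QC
#'   estimates), `analyses` (per-run `plate_analysis` objects).
#' @export
analyze_validation_study <- function(study_dir, channel = "blue", ...) {
  index_path <- file.path(study_dir, "study.csv")
  if (!file.exists(index_path)) {
    stop("not a study directory: missing ", index_path, call. = FALSE)
  }
  index <- readr::read_csv(index_path, col_types = readr::cols())
  missing_runs <- index$run_id[!file.exists(file.path(study_dir, index$image))]
  if (length(missing_runs)) {
    stop("incomplete study: missing image(s) for run(s) ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  }
  analyses <- purrr::map(seq_len(nrow(index)), function(i) {
    analyze_plate(file.path(study_dir, index$image[i]),
                  file.path(study_dir, index$plate_map[i]),
                  file.path(study_dir, index$layout[i]),
                  channel = channel, ...)
  })
  names(analyses) <- index$run_id
  results <- purrr::imap_dfr(analyses, function(an, run_id) {
    an$results |>
      dplyr::filter(.data$method == "direct", !is.na(.data$nominal_conc)) |>
      dplyr::mutate(run_id = run_id, .before = 1)
  })
  if (length(unique(results$run_id)) < 2L) {
    stop("intermediate precision needs >= 2 runs; study has ",
         length(unique(results$run_id)), call. = FALSE)
  }
  linearity <- purrr::imap_dfr(analyses, function(an, run_id) {
    ch <- unique(an$results$channel)[1]
    cv <- an$curves[[1]][[ch]]
    tibble::tibble(run_id = run_id, r_squared = cv$r_squared,
                   range_lo = cv$linear_range[1],
                   range_hi = cv$linear_range[2])
  })
  report <- build_validation_report(results, linearity)
  list(report = report, results = results, analyses = analyses)
}
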