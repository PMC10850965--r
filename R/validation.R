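#' Coefficient of variation in percent
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation, the convention of analytical-method validation at small n.
#'
#' @param values Numeric vector, at least 2 values with a positive mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) {
    stop("insufficient data: CV needs at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("CV undefined: mean must be positive", call. = FALSE)
  }
  100 * stats::sd(values) / m
}

#' Build a validation report from replicate quantification runs
#'
#' Summarises intermediate precision (CV% across runs), accuracy (percent
#' bias of the mean estimate against nominal) and, when per-run linearity
#' is supplied, the calibration quality per run.
#'
#' @param results Data frame with one row per (run, QC level): columns
#'   `run_id`, `nominal_conc` (% w/w) and `estimate` (% w/w). Every level
#'   needs at least 2 runs.
#' @param linearity Optional data frame with columns `run_id`, `r_squared`,
#'   `range_lo`, `range_hi` describing each run's own in-photo calibration.
#' @return An object of class `validation_report`: `per_level` tibble
#'   (`nominal_conc`, `n`, `mean_measured`, `cv_percent`, `bias_percent`),
#'   `linearity` tibble (possibly empty) and `overall` list
#'   (`max_abs_bias`, `max_cv`, `min_r_squared`).
#' @export
build_validation_report <- function(results, linearity = NULL) {
  stopifnot(is.data.frame(results),
            all(c("run_id", "nominal_conc", "estimate") %in% names(results)))
  counts <- dplyr::count(results, .data$nominal_conc)
  if (any(counts$n < 2L)) {
    stop("intermediate precision needs >= 2 runs per level; level(s) ",
         paste(counts$nominal_conc[counts$n < 2L], collapse = ", "),
         " have fewer", call. = FALSE)
  }
  per_level <- results |>
    dplyr::group_by(nominal_conc = .data$nominal_conc) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_measured = mean(.data$estimate),
      cv_percent = cv_percent(.data$estimate),
      .groups = "drop") |>
    dplyr::mutate(
      bias_percent = bias_percent(.data$mean_measured, .data$nominal_conc)) |>
    dplyr::arrange(.data$nominal_conc)
  if (is.null(linearity)) {
    linearity <- tibble::tibble(run_id = character(), r_squared = numeric(),
                                range_lo = numeric(), range_hi = numeric())
  }
  structure(list(
    per_level = per_level,
    linearity = tibble::as_tibble(linearity),
    overall = list(
      max_abs_bias = max(abs(per_level$bias_percent)),
      max_cv = max(per_level$cv_percent),
      min_r_squared = if (nrow(linearity)) min(linearity$r_squared) else NA_real_)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$per_level)
  cat(sprintf("overall: max |bias| %.2f%%, max CV %.2f%%",
              x$overall$max_abs_bias, x$overall$max_cv))
  if (is.finite(x$overall$min_r_squared %||% NA_real_)) {
    cat(sprintf(", min R^2 %.4f", x$overall$min_r_squared))
  }
  cat("\n")
  invisible(x)
}

#' @rdname build_validation_report
#' @param x A `validation_report`.
#' @param ... Unused.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$per_level

#' @rdname build_validation_report
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(max_abs_bias = x$overall$max_abs_bias,
                 max_cv = x$overall$max_cv,
                 min_r_squared = x$overall$min_r_squared,
                 n_levels = nrow(x$per_level))
}

#' Plot per-level precision and accuracy
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object (CV% and bias% per QC level).
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  long <- object$per_level |>
    tidyr::pivot_longer(c("cv_percent", "bias_percent"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$nominal_conc,
                                     y = .data$value)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "QC level (% w/w)", y = "percent") +
    ggplot2::theme_minimal()
}

#' Write a validation report
#'
#' `write_validation_json()` dumps the full report; `write_validation_csv()`
#' writes the per-level table in the conventional layout (level, CV, mean
#' measured, bias, per-study linearity appended as comment-free columns).
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(list(per_level = report$per_level,
                            linearity = report$linearity,
                            overall = report$overall),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_validation_json
#' @export
write_validation_csv <- function(report, path) {
  tab <- report$per_level[, c("nominal_conc", "cv_percent", "n",
                              "mean_measured", "bias_percent")]
  readr::write_csv(tab, path)
  invisible(path)
}
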