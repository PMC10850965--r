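#' Ordinary least-squares line fit of signal on concentration
#'
#' @param x,y Numeric vectors (concentration in % w/w and channel signal);
#'   at least 3 points with at least 2 distinct `x`.
#' @return A list with `slope`, `intercept`, `r_squared`
#'   (`1 - SSE/SST`).
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    stop("insufficient data: OLS calibration needs at least 3 points",
         call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("insufficient data: need at least 2 distinct x values",
         call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("degenerate fit: all signals identical (SST = 0)", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = 1 - sse / sst)
}

#' Construct a calibration curve from known parameters
#'
#' Useful for encoding a previously characterised calibration (e.g. a
#' published channel equation) without refitting; [determine_linear_range()]
#' builds curves from data.
#'
#' @param channel One of [dic_channels()].
#' @param slope,intercept Line parameters (signal = intercept + slope * c).
#' @param r_squared Coefficient of determination in `[0, 1]`.
#' @param linear_range Length-2 numeric `(c_lo, c_hi)` in % w/w.
#' @param matrix Matrix label.
#' @param points Optional tibble of `(conc, signal, retained)` fit points.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(channel, slope, intercept, r_squared,
                              linear_range, matrix = "unspecified",
                              points = NULL) {
  channel <- match.arg(channel, dic_channels())
  stopifnot(r_squared >= 0, r_squared <= 1, length(linear_range) == 2,
            linear_range[1] < linear_range[2])
  if (is.null(points)) {
    points <- tibble::tibble(conc = numeric(), signal = numeric(),
                             retained = logical())
  }
  new_calibration_curve(channel, slope, intercept, r_squared,
                        as.numeric(linear_range), matrix,
                        tibble::as_tibble(points))
}

new_calibration_curve <- function(channel, slope, intercept, r_squared,
                                  linear_range, matrix, points) {
  structure(list(
    channel = channel, slope = slope, intercept = intercept,
    r_squared = r_squared, linear_range = linear_range, matrix = matrix,
    points = points
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s channel in '%s': signal = %.4g %+.4g c, R^2 = %.4f\n",
    x$channel, x$matrix, x$intercept, x$slope, x$r_squared))
  cat(sprintf("  linear range %.4g - %.4g %% w/w (%d points retained)\n",
              x$linear_range[1], x$linear_range[2],
              sum(x$points$retained)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of terms (intercept, slope); `glance()`: a
#'   one-row fit summary with the linear range.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.calibration_curve
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(channel = x$channel, matrix = x$matrix, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 range_lo = x$linear_range[1], range_hi = x$linear_range[2],
                 n_retained = sum(x$points$retained),
                 n_dropped = sum(!x$points$retained))
}

#' Plot a calibration curve
#'
#' Retained standards, dropped standards and the fitted line over the
#' linear range.
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc, y = .data$signal,
                                    shape = .data$retained)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(
      x = "concentration (% w/w)",
      y = paste(object$channel, "signal (0-255)"),
      shape = "retained",
      title = sprintf("%s channel, %s (R² = %.3f)", object$channel,
                      object$matrix, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Back-calculate concentration from a calibration curve
#'
#' Inverts the fitted line, `c = (signal - intercept) / slope`, and flags
#' results falling outside the curve's linear range beyond a tolerance band
#' (default 10% of the respective range endpoint, so a zero-concentration
#' estimate against a 2.5-30 range is always flagged).
#'
#' @param curve A `calibration_curve` with nonzero slope.
#' @param signal Numeric vector of channel signals.
#' @param range_tol_frac Tolerance band as a fraction of each linear-range
#'   endpoint.
#' @return A tibble with `signal`, `estimate` (% w/w) and `out_of_range`.
#' @export
back_calculate <- function(curve, signal, range_tol_frac = 0.10) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    stop("degenerate curve: slope is zero, cannot back-calculate",
         call. = FALSE)
  }
  est <- (signal - curve$intercept) / curve$slope
  lo <- curve$linear_range[1] * (1 - range_tol_frac)
  hi <- curve$linear_range[2] * (1 + range_tol_frac)
  tibble::tibble(signal = signal, estimate = est,
                 out_of_range = est < lo | est > hi)
}

#' Determine the linear dynamic range by endpoint trimming
#'
#' Fits all standards, back-calculates each against the fit, and while the
#' fit fails either acceptance criterion (`r_squared >= r2_min` and every
#' standard back-calculated within `backcalc_bias_max` percent of nominal)
#' drops the endpoint concentration and refits. The low-concentration end
#' is trimmed first -- in this assay the proportionality between dye colour
#' and analyte is lost at low analyte levels -- and the high end only once
#' the low end passes its bias check. Replicates at an endpoint
#' concentration are dropped together. Stops with an error when fewer than
#' 3 standards would remain.
#'
#' @param standards Data frame with columns `conc` (% w/w) and `signal`;
#'   at least 4 standards spanning at least 3 distinct concentrations.
#'   Blank (zero-concentration) standards are not accepted as calibration
#'   points.
#' @param r2_min Minimum coefficient of determination.
#' @param backcalc_bias_max Maximum tolerated per-standard back-calculation
#'   bias, in percent.
#' @param channel,matrix Labels stored on the returned curve.
#' @return A `calibration_curve`; `points` records every input standard
#'   with a `retained` flag, `linear_range` is the span of retained
#'   concentrations.
#' @export
determine_linear_range <- function(standards, r2_min = 0.98,
                                   backcalc_bias_max = 15,
                                   channel = "blue", matrix = "unspecified") {
  stopifnot(is.data.frame(standards),
            all(c("conc", "signal") %in% names(standards)))
  standards <- tibble::as_tibble(standards[, c("conc", "signal")])
  if (any(standards$conc <= 0)) {
    stop("calibration standards must have positive concentration ",
         "(blanks are diagnostics, not fit points)", call. = FALSE)
  }
  if (nrow(standards) < 4L || length(unique(standards$conc)) < 3L) {
    stop("insufficient data: need >= 4 standards over >= 3 distinct ",
         "concentrations", call. = FALSE)
  }
  standards <- dplyr::arrange(standards, .data$conc)
  retained <- rep(TRUE, nrow(standards))
  repeat {
    cur <- standards[retained, ]
    if (nrow(cur) < 3L || length(unique(cur$conc)) < 2L) {
      stop("no linear range: no subset of >= 3 standards satisfies ",
           sprintf("R^2 >= %g and |bias| <= %g%%", r2_min, backcalc_bias_max),
           call. = FALSE)
    }
    fit <- tryCatch(fit_line(cur$conc, cur$signal), error = function(e) NULL)
    if (!is.null(fit)) {
      pred_c <- (cur$signal - fit$intercept) / fit$slope
      bias <- 100 * (pred_c - cur$conc) / cur$conc
      lo_bad <- any(abs(bias[cur$conc == min(cur$conc)]) > backcalc_bias_max)
      hi_bad <- any(abs(bias[cur$conc == max(cur$conc)]) > backcalc_bias_max)
      mid_bad <- any(abs(bias) > backcalc_bias_max)
      if (fit$r_squared >= r2_min && !mid_bad) {
        rng <- range(cur$conc)
        pts <- dplyr::mutate(standards, retained = retained)
        return(new_calibration_curve(channel, fit$slope, fit$intercept,
                                     fit$r_squared, rng, matrix, pts))
      }
      drop_hi <- !lo_bad && hi_bad
    } else {
      drop_hi <- FALSE                   # degenerate fit: trim the low end
    }
    drop_conc <- if (drop_hi) max(cur$conc) else min(cur$conc)
    retained <- retained & standards$conc != drop_conc
  }
}

#' Select the analytical channel among candidate calibrations
#'
#' Among candidate curves with `r_squared >= r2_min`, keeps those whose
#' linear range spans the widest concentration interval and returns the
#' one with the largest absolute slope (highest sensitivity). Hue is
#' excluded a priori: it carries no usable linear dependence on analyte
#' concentration in this assay.
#'
#' @param curves Named list of `calibration_curve` objects (names are
#'   channel names) or an unnamed list (channels taken from the curves).
#' @param r2_min Minimum acceptable coefficient of determination.
#' @return The name of the selected channel.
#' @export
select_channel <- function(curves, r2_min = 0.98) {
  curves <- purrr::keep(curves, ~ inherits(.x, "calibration_curve"))
  curves <- purrr::keep(curves, ~ .x$channel != "hue")
  ok <- purrr::keep(curves, ~ .x$r_squared >= r2_min)
  if (!length(ok)) {
    stop("selection error: no candidate channel reaches R^2 >= ", r2_min,
         call. = FALSE)
  }
  spans <- purrr::map_dbl(ok, ~ diff(.x$linear_range))
  widest <- purrr::keep(ok, ~ diff(.x$linear_range) >= max(spans) - 1e-9)
  slopes <- purrr::map_dbl(widest, ~ abs(.x$slope))
  widest[[which.max(slopes)]]$channel
}

#' Fit candidate calibrations from a plate observation table
#'
#' Takes the valid `standard` wells of one matrix and fits a trimmed
#' calibration per requested channel via [determine_linear_range()].
#'
#' @param observations Observation tibble from [read_plate()].
#' @param channels Channels to fit (default: every candidate except hue).
#' @param matrix Matrix label to calibrate; default the single matrix
#'   present among standards (error if ambiguous).
#' @param r2_min,backcalc_bias_max Passed to [determine_linear_range()].
#' @return Named list of `calibration_curve` objects; channels for which no
#'   linear range exists are dropped with a warning.
#' @export
fit_calibration <- function(observations, channels = setdiff(dic_channels(), "hue"),
                            matrix = NULL, r2_min = 0.98,
                            backcalc_bias_max = 15) {
  std <- dplyr::filter(observations, .data$role == "standard", .data$valid)
  if (is.null(matrix)) {
    mats <- unique(std$matrix)
    if (length(mats) != 1L) {
      stop("standards cover ", length(mats),
           " matrices; pass `matrix` explicitly", call. = FALSE)
    }
    matrix <- mats
  }
  std <- dplyr::filter(std, .data$matrix == !!matrix, .data$nominal_conc > 0)
  if (!nrow(std)) {
    stop("cannot calibrate: no valid standard wells for matrix '", matrix,
         "'", call. = FALSE)
  }
  curves <- purrr::map(rlang::set_names(channels), function(ch) {
    pts <- tibble::tibble(conc = std$nominal_conc,
                          signal = std[[channel_column(ch)]])
    tryCatch(
      determine_linear_range(pts, r2_min = r2_min,
                             backcalc_bias_max = backcalc_bias_max,
                             channel = ch, matrix = matrix),
      error = function(e) {
        warning("channel ", ch, " dropped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  })
  purrr::compact(curves)
}

#' Write calibration curves as JSON
#'
#' One record per (matrix, channel) with slope, intercept, R^2, linear
#' range and the retained/dropped points; the companion
#' [write_channel_comparison()] writes a cross-channel comparison CSV.
#'
#' @param curves Named list of `calibration_curve`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curves, path) {
  recs <- purrr::map(curves, function(cv) list(
    channel = cv$channel, matrix = cv$matrix, slope = cv$slope,
    intercept = cv$intercept, r_squared = cv$r_squared,
    linear_range = cv$linear_range,
    points = cv$points))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
write_channel_comparison <- function(curves, path) {
  readr::write_csv(purrr::map_dfr(curves, glance), path)
  invisible(path)
}
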