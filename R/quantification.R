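#' Percent bias of a measured value against nominal
#'
#' `100 * (measured - nominal) / nominal`. Vectorised.
#'
#' @param measured,nominal Numeric, % w/w; `nominal` must be positive.
#' @return Numeric vector of percent biases.
#' @export
bias_percent <- function(measured, nominal) {
  if (any(!is.finite(nominal)) || any(nominal <= 0)) {
    stop("nominal concentration must be positive", call. = FALSE)
  }
  100 * (measured - nominal) / nominal
}

new_quant_result <- function(sample_id, method, channel, estimate, r_squared,
                             out_of_range, extrapolation_flag = FALSE) {
  tibble::tibble(
    sample_id = sample_id, method = method, channel = channel,
    estimate = estimate, r_squared = r_squared,
    out_of_range = out_of_range, extrapolation_flag = extrapolation_flag)
}

#' Quantify by direct calibration
#'
#' Averages replicate signals first, then back-calculates through the
#' calibration curve; the out-of-range flag of [back_calculate()] is
#' propagated.
#'
#' @param curve A `calibration_curve`.
#' @param signals Numeric vector of replicate channel signals for one
#'   sample.
#' @param sample_id Label for the result row.
#' @return A one-row tibble: `sample_id`, `method` (`"direct"`), `channel`,
#'   `estimate` (% w/w), `r_squared` (the curve's), `out_of_range`,
#'   `extrapolation_flag`.
#' @export
quantify_direct <- function(curve, signals, sample_id = "sample") {
  stopifnot(inherits(curve, "calibration_curve"), length(signals) >= 1)
  bc <- back_calculate(curve, mean(signals))
  new_quant_result(sample_id, "direct", curve$channel, bc$estimate,
                   curve$r_squared, bc$out_of_range)
}

#' Define a standard-addition design with a nonzero reference standard
#'
#' Classical standard addition extrapolates the fitted addition line to the
#' zero-analyte signal. When the assay loses linearity below a
#' concentration floor (here ~2.5 % w/w analyte), that extrapolation is
#' invalid; instead the design carries a calibration reference standard at
#' a concentration above the floor, prepared in the same matrix and
#' photographed in the same image, and the estimator extrapolates to the
#' reference signal.
#'
#' @param additions Data frame with columns `added_conc` (% w/w spiked
#'   into aliquots of the unknown; an unspiked `0` aliquot is allowed) and
#'   `signal`; at least 3 aliquots over at least 2 distinct additions.
#' @param ref_conc Reference-standard concentration, % w/w.
#' @param ref_signal Reference-standard signal(s); replicates are averaged.
#' @param channel,matrix Labels.
#' @param range_lo Lower limit of the matrix's linear range used to
#'   validate `ref_conc` (default 2.5 % w/w).
#' @return An object of class `standard_addition_design`.
#' @export
standard_addition_design <- function(additions, ref_conc, ref_signal,
                                     channel = "blue",
                                     matrix = "unspecified",
                                     range_lo = 2.5) {
  stopifnot(is.data.frame(additions),
            all(c("added_conc", "signal") %in% names(additions)))
  additions <- tibble::as_tibble(additions[, c("added_conc", "signal")])
  if (nrow(additions) < 3L || length(unique(additions$added_conc)) < 2L) {
    stop("insufficient design: need >= 3 spiked aliquots over >= 2 ",
         "distinct additions", call. = FALSE)
  }
  sigs <- c(additions$signal, ref_signal)
  if (any(sigs < 0 | sigs > 255)) {
    stop("signals must lie on the 0-255 intensity scale", call. = FALSE)
  }
  if (ref_conc < range_lo) {
    stop("reference standard at ", ref_conc, " % w/w is below the ",
         "linear-range floor (", range_lo, " % w/w); extrapolation to it ",
         "would not be valid", call. = FALSE)
  }
  structure(list(additions = additions, ref_conc = ref_conc,
                 ref_signal = mean(ref_signal), channel = channel,
                 matrix = matrix),
            class = "standard_addition_design")
}

#' @export
print.standard_addition_design <- function(x, ...) {
  cat(sprintf(
    "<standard_addition_design> %d aliquots (x = %s %% w/w), reference %g %% w/w at signal %.2f, %s channel, '%s'\n",
    nrow(x$additions),
    paste(sort(unique(x$additions$added_conc)), collapse = ", "),
    x$ref_conc, x$ref_signal, x$channel, x$matrix))
  invisible(x)
}

#' Quantify by modified standard addition
#'
#' Fits the addition line `y = a + b x` by OLS over the spiked aliquots and
#' estimates the unknown as
#' \deqn{c_0 = c_{ref} + (a - y_{ref}) / b.}
#' Under a shared linear response `y = alpha + beta (c0 + x)` measured in
#' the same photo as the reference (`y_ref = alpha + beta c_ref`,
#' `beta = b`), the formula is exact for either sign of the slope; with
#' `c_ref = 0` and `y_ref = alpha` it reduces to classical
#' standard-addition extrapolation.
#'
#' @param design A [standard_addition_design()].
#' @param linear_range Optional length-2 numeric; when supplied, the result
#'   is flagged out-of-range if `c0` falls below its lower limit and
#'   `extrapolation_flag` is set if `c0 + max(added_conc)` exceeds its
#'   upper limit.
#' @param r2_min Addition-line fits below this R^2 set `out_of_range`'s
#'   companion diagnostic `r_squared` but also flag the estimate.
#' @param sample_id Label for the result row.
#' @return A one-row tibble as in [quantify_direct()], `method`
#'   `"standard_addition"`.
#' @export
quantify_standard_addition <- function(design, linear_range = NULL,
                                       r2_min = 0.98,
                                       sample_id = "sample") {
  stopifnot(inherits(design, "standard_addition_design"))
  fit <- fit_line(design$additions$added_conc, design$additions$signal)
  if (fit$slope == 0) {
    stop("degenerate slope: addition line is flat", call. = FALSE)
  }
  c0 <- design$ref_conc + (fit$intercept - design$ref_signal) / fit$slope
  out_of_range <- fit$r_squared < r2_min
  extrap <- FALSE
  if (!is.null(linear_range)) {
    out_of_range <- out_of_range || c0 < linear_range[1]
    extrap <- c0 + max(design$additions$added_conc) > linear_range[2]
  }
  new_quant_result(sample_id, "standard_addition", design$channel, c0,
                   fit$r_squared, out_of_range, extrap)
}
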