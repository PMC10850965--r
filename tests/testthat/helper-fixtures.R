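# Shared fixtures and independent oracles.

# closed-form OLS, independent of fit_line's lm route
ols_brute <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  sse <- sum((y - a - b * x)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = 1 - sse / sst)
}

# classical standard addition: extrapolate the addition line to the
# zero-analyte signal alpha, c0 = (a - alpha) / b
classical_standard_addition <- function(added, signal, alpha) {
  f <- ols_brute(added, signal)
  (f$intercept - alpha) / f$slope
}

uniform_roi <- function(n, rgb) {
  tibble::tibble(red = rep(rgb[1], n), green = rep(rgb[2], n),
                 blue = rep(rgb[3], n))
}

# one-row strip plate map over the given concentrations, all standards
standards_map <- function(concs, matrix = "cream B", role = "standard") {
  tibble::tibble(
    well_id = sprintf("W%02d", seq_along(concs)),
    role = role, matrix = matrix,
    nominal_conc = concs, added_conc = NA_real_)
}

# render a single-row strip of standards and read it back
render_and_read <- function(model, concs, seed, refine = TRUE, ...) {
  layout <- well_layout(n_rows = 1, n_cols = length(concs))
  pm <- standards_map(concs)
  ren <- render_plate(model, pm, layout, seed = seed)
  lay <- if (refine) locate_wells(ren$image, layout) else layout
  list(obs = read_plate(ren$image, lay, pm, ...), render = ren,
       layout = lay, plate_map = pm, grid = layout)
}

noiseless_model <- function(...) {
  response_model(pixel_noise_sd = 0, well_gain_sd = 0, run_gain_sd = 0, ...)
}

table2_curves <- function() {
  list(
    red = calibration_curve("red", -0.255, 187.04, 0.975, c(8.1, 30.0)),
    green = calibration_curve("green", -0.452, 171.90, 0.966, c(8.1, 30.0)),
    blue = calibration_curve("blue", -3.009, 128.19, 0.992, c(2.5, 30.0)),
    rgb_mean = calibration_curve("rgb_mean", -1.156, 160.31, 0.990,
                                 c(2.5, 30.0)),
    saturation = calibration_curve("saturation", 4.185, 79.49, 0.991,
                                   c(2.5, 30.0)),
    brightness = calibration_curve("brightness", -0.161, 185.96, 0.966,
                                   c(2.5, 27.2))
  )
}
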