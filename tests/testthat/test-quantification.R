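test_that("direct quantification averages replicates then inverts", {
  curve <- calibration_curve("blue", -3.009, 128.19, 0.992, c(2.5, 30.0))
  res <- quantify_direct(curve, c(98.0, 98.2), sample_id = "qc10")
  expect_equal(res$estimate, (128.19 - 98.1) / 3.009, tolerance = 1e-12)
  expect_equal(res$method, "direct")
  expect_false(res$out_of_range)

  # a signal mapping far past the range upper limit is flagged
  res45 <- quantify_direct(curve, 128.19 - 3.009 * 45)
  expect_equal(res45$estimate, 45, tolerance = 1e-9)
  expect_true(res45$out_of_range)
})

test_that("bias_percent matches hand arithmetic and guards the domain", {
  expect_equal(bias_percent(6.03, 6.03), 0)
  expect_equal(bias_percent(11.09, 10.0), 10.90, tolerance = 1e-9)
  expect_equal(bias_percent(2.26, 2.50), -9.60, tolerance = 1e-9)
  expect_error(bias_percent(5, 0), "positive")
  expect_error(bias_percent(5, -1), "positive")
})

test_that("standard addition with a nonzero reference is exact on linear data", {
  # alpha = 130, beta = -3, c0 = 10; reference at 5 reads 115
  d <- standard_addition_design(
    tibble::tibble(added_conc = c(0, 5, 10), signal = 100 - 3 * c(0, 5, 10)),
    ref_conc = 5, ref_signal = 115)
  expect_equal(quantify_standard_addition(d)$estimate, 10, tolerance = 1e-12)

  # saturation-style positive slope: alpha = 79.49, beta = 4.185, c0 = 8
  d2 <- standard_addition_design(
    tibble::tibble(added_conc = c(0, 4, 8, 12),
                   signal = 112.97 + 4.185 * c(0, 4, 8, 12)),
    ref_conc = 10, ref_signal = 121.34)
  expect_equal(quantify_standard_addition(d2)$estimate,
               10 + (112.97 - 121.34) / 4.185, tolerance = 1e-12)
  expect_equal(quantify_standard_addition(d2)$estimate, 8, tolerance = 1e-9)
})

test_that("the estimator is exact for any in-range linear design", {
  set.seed(202)
  for (i in 1:30) {
    # parameter windows keep every signal on the 8-bit scale
    up <- sample(c(TRUE, FALSE), 1)
    beta <- (if (up) 1 else -1) * runif(1, 0.5, 2.5)
    alpha <- if (up) runif(1, 60, 120) else runif(1, 100, 160)
    c0 <- runif(1, 3, 20)
    c_ref <- runif(1, 2.6, 28)
    adds <- sort(runif(4, 0, 12))
    sig <- function(conc) alpha + beta * conc
    d <- standard_addition_design(
      tibble::tibble(added_conc = adds, signal = sig(c0 + adds)),
      ref_conc = c_ref, ref_signal = sig(c_ref))
    expect_equal(quantify_standard_addition(d)$estimate, c0,
                 tolerance = 1e-9)
  }
})

test_that("with a zero reference the estimator reduces to classical form", {
  set.seed(303)
  for (i in 1:10) {
    beta <- sample(c(-1, 1), 1) * runif(1, 0.5, 5)
    alpha <- runif(1, 60, 160)
    c0 <- runif(1, 2, 15)
    adds <- c(0, 3, 6, 9)
    sig <- alpha + beta * (c0 + adds)
    d <- standard_addition_design(
      tibble::tibble(added_conc = adds, signal = sig),
      ref_conc = 0, ref_signal = alpha, range_lo = 0)
    expect_equal(quantify_standard_addition(d)$estimate,
                 classical_standard_addition(adds, sig, alpha),
                 tolerance = 1e-9)
  }
})

test_that("design invariants are enforced", {
  adds <- tibble::tibble(added_conc = c(0, 5, 10), signal = c(100, 85, 70))
  expect_error(standard_addition_design(adds[1:2, ], 5, 110),
               "insufficient design")
  expect_error(standard_addition_design(
    tibble::tibble(added_conc = c(5, 5, 5), signal = c(1, 2, 3)), 5, 110),
    "insufficient design")
  expect_error(standard_addition_design(adds, ref_conc = 1, ref_signal = 120),
               "below the")
  expect_error(standard_addition_design(adds, 5, ref_signal = 300),
               "0-255")
  flat <- standard_addition_design(
    tibble::tibble(added_conc = c(0, 5, 10), signal = c(100, 100, 100.0001)),
    5, 110)
  expect_error(quantify_standard_addition(
    standard_addition_design(
      tibble::tibble(added_conc = c(0, 5, 10), signal = c(100, 100, 100)),
      5, 110)), "SST = 0")
  expect_s3_class(flat, "standard_addition_design")
})

test_that("a simulated spiked run recovers the true content within the assay bias", {
  m <- response_model()
  layout <- well_layout(n_rows = 1, n_cols = 12)
  pm <- tibble::tibble(
    well_id = sprintf("W%02d", 1:12),
    role = c(rep("standard", 7), rep("spiked_sample", 4),
             "reference_standard"),
    matrix = "cream B",
    nominal_conc = c(2.52, 6.03, 10.07, 18.13, 23.32, 27.21, 30.03,
                     rep(10, 4), 10),
    added_conc = c(rep(NA, 7), 0, 5, 10, 15, NA))
  ren <- render_plate(m, pm, layout, seed = 7)
  an <- analyze_plate(ren$image, pm, layout, channel = "blue")
  sa <- dplyr::filter(an$results, method == "standard_addition")
  expect_equal(nrow(sa), 1)
  # worst characterised bias of the assay's spiked-recovery studies
  expect_lt(abs(bias_percent(sa$estimate, 10)), 10.91)
})

test_that("direct and standard-addition estimates agree on a shared photo", {
  m <- response_model()
  layout <- well_layout(n_rows = 1, n_cols = 13)
  pm <- tibble::tibble(
    well_id = sprintf("W%02d", 1:13),
    role = c(rep("standard", 7), "qc", rep("spiked_sample", 4),
             "reference_standard"),
    matrix = "cream B",
    nominal_conc = c(2.52, 6.03, 10.07, 18.13, 23.32, 27.21, 30.03,
                     10, rep(10, 4), 10),
    added_conc = c(rep(NA, 7), NA, 0, 5, 10, 15, NA))
  ren <- render_plate(m, pm, layout, seed = 8)
  an <- analyze_plate(ren$image, pm, layout, channel = "blue")
  direct <- dplyr::filter(an$results, method == "direct")$estimate
  sa <- dplyr::filter(an$results,
                      method == "standard_addition")$estimate
  expect_lt(abs(direct - sa), 1.5)      # both estimate the same 10 % w/w truth
})
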