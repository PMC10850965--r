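concs8 <- c(2.52, 6.03, 10.07, 14.0, 18.13, 23.32, 27.21, 30.03)

test_that("expected_signal evaluates the clipped linear response", {
  m <- response_model()
  expect_equal(expected_signal(m, "blue", 10.0), 128.19 - 30.09,
               tolerance = 1e-12)
  # below the clip the response is flat at the 2.52 % w/w value
  expect_equal(expected_signal(m, "blue", 1.0),
               expected_signal(m, "blue", 2.52))
  expect_equal(expected_signal(m, "blue", 1.0), 128.19 - 3.009 * 2.52,
               tolerance = 1e-12)
  # above the upper clip the response saturates
  expect_equal(expected_signal(m, "red", m$channels$red$clip_hi),
               expected_signal(m, "red", 60))
  expect_error(expected_signal(m, "blue", -1))
})

test_that("rendering is deterministic in the seed", {
  m <- response_model(glare_prob = 0.3, bubble_prob = 0.3)
  layout <- well_layout(n_rows = 1, n_cols = 4)
  pm <- standards_map(c(6, 10, 20, 30))
  a <- render_plate(m, pm, layout, seed = 42)
  b <- render_plate(m, pm, layout, seed = 42)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$manifest$wells, b$manifest$wells)
  c <- render_plate(m, pm, layout, seed = 43)
  expect_false(identical(a$image$pixels, c$image$pixels))
  expect_error(render_plate(m, pm, layout), "seed")
})

test_that("noiseless ROI means sit within quantisation of the response", {
  rr <- render_and_read(noiseless_model(), concs8, seed = 1)
  expected <- expected_signal(noiseless_model(), "blue", concs8)
  expect_lt(max(abs(rr$obs$blue_mean - expected)), 0.5)
})

test_that("round trip recovers the blue response parameters", {
  rr <- render_and_read(noiseless_model(), concs8, seed = 1)
  f <- fit_line(rr$obs$nominal_conc, rr$obs$blue_mean)
  expect_lt(abs(f$slope - (-3.009)), 0.02)
  expect_lt(abs(f$intercept - 128.19), 0.6)
  expect_gt(f$r_squared, 0.999)
})

test_that("saturation emerges linear in concentration on noiseless renders", {
  rr <- render_and_read(noiseless_model(), concs8, seed = 2)
  f <- fit_line(rr$obs$nominal_conc, rr$obs$saturation_mean)
  expect_gt(f$r_squared, 0.98)
  expect_gt(f$slope, 0)                 # saturation rises with analyte
})

test_that("glare artifacts are recorded and masked by the pipeline", {
  m <- response_model(glare_prob = 1)
  layout <- well_layout(n_rows = 1, n_cols = 4)
  pm <- standards_map(c(6, 10, 20, 30))
  ren <- render_plate(m, pm, layout, seed = 3)
  expect_true(all(ren$manifest$wells$glare))
  obs <- read_plate(ren$image, layout, pm)
  expect_true(all(obs$masked_fraction > 0))
})

test_that("a shared run gain cancels out of quantification", {
  cvs <- vapply(c(0, 0.5), function(rg) {
    mm <- response_model(run_gain_sd = rg)
    dd <- withr::local_tempdir()
    simulate_validation_study(mm, levels = 6.03, n_runs = 6, dir = dd,
                              seed = 5)
    rr <- analyze_validation_study(dd, channel = "blue")
    rr$report$per_level$cv_percent
  }, numeric(1))
  expect_lt(cvs[2], 2 * cvs[1])
})

test_that("a noiseless study is recovered to within quantisation", {
  m0 <- noiseless_model()
  dd <- withr::local_tempdir()
  simulate_validation_study(m0, levels = c(6.03, 18.13, 30.03), n_runs = 2,
                            dir = dd, seed = 3)
  rr <- analyze_validation_study(dd, channel = "blue")
  # 8-bit quantisation permits up to 0.5 intensity of well-mean error,
  # i.e. 0.5/|slope| in concentration
  expect_lt(max(abs(rr$results$estimate - rr$results$nominal_conc)),
            0.5 / 3.009)
})

test_that("study generation writes a complete, reproducible file set", {
  m <- response_model()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  idx <- simulate_validation_study(m, levels = c(6.03, 10.07), n_runs = 2,
                                   dir = d1, seed = 11)
  simulate_validation_study(m, levels = c(6.03, 10.07), n_runs = 2,
                            dir = d2, seed = 11)
  expect_equal(nrow(idx), 2)
  for (f in c("study.csv", "layout.yaml", "run01.png", "run01_map.csv",
              "run01_manifest.json", "run02.png")) {
    expect_true(file.exists(file.path(d1, f)))
  }
  expect_identical(unname(tools::md5sum(file.path(d1, "run01.png"))),
                   unname(tools::md5sum(file.path(d2, "run01.png"))))
  # layouts round trip through YAML
  lay <- read_layout_yaml(file.path(d1, "layout.yaml"))
  expect_equal(lay$n_wells, 9)          # 7 standards + 2 QC wells
  expect_error(simulate_validation_study(m, levels = 40, n_runs = 2,
                                         dir = d1, seed = 1), "levels")
})

test_that("overlapping wells are rejected at layout construction", {
  expect_error(well_layout(n_rows = 1, n_cols = 4, pitch_px = 50,
                           well_radius_px = 30), "overlap")
})
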