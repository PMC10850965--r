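concs8 <- c(2.52, 6.03, 10.07, 14.0, 18.13, 23.32, 27.21, 30.03)

test_that("locate_wells recovers rendered centres from an exact grid", {
  m <- noiseless_model()
  layout <- well_layout(n_rows = 1, n_cols = 8)
  pm <- standards_map(concs8)
  ren <- render_plate(m, pm, layout, seed = 1)
  refined <- locate_wells(ren$image, layout)
  truth <- ren$manifest$wells
  expect_lt(max(abs(refined$centers$row - truth$center_row)), 1)
  expect_lt(max(abs(refined$centers$col - truth$center_col)), 1)
})

test_that("locate_wells corrects a 5 px grid offset to within 2 px", {
  m <- noiseless_model()
  layout <- well_layout(n_rows = 1, n_cols = 8)
  pm <- standards_map(concs8)
  ren <- render_plate(m, pm, layout, seed = 2)
  off <- layout
  off$centers$row <- layout$centers$row + 5
  off$centers$col <- layout$centers$col - 5
  refined <- locate_wells(ren$image, off)
  truth <- ren$manifest$wells
  expect_lt(max(abs(refined$centers$row - truth$center_row)), 2)
  expect_lt(max(abs(refined$centers$col - truth$center_col)), 2)
})

test_that("a grid placing wells outside the image is a layout error", {
  expect_error(well_layout(n_rows = 1, n_cols = 8, pitch_px = 70,
                           first_center_px = c(20, 60)),
               "layout error")
  # refinement pushing an edge ROI out is also caught
  m <- noiseless_model()
  layout <- well_layout(n_rows = 1, n_cols = 2)
  ren <- render_plate(m, standards_map(c(10, 20)), layout, seed = 1)
  shrunk <- layout
  shrunk$image_size <- c(120L, 120L)
  expect_error(locate_wells(ren$image, shrunk), "does not match")
})

test_that("mask_artifacts masks glare discs and nothing on uniform fields", {
  roi <- uniform_roi(2000, c(100, 80, 60))
  expect_equal(sum(mask_artifacts(roi)), 0)

  glare_n <- 100                        # 5% of area
  roi_g <- dplyr::bind_rows(uniform_roi(1900, c(100, 80, 60)),
                            uniform_roi(glare_n, c(255, 255, 255)))
  masked <- mask_artifacts(roi_g)
  expect_equal(which(masked), 1901:2000)
  st <- roi_channel_stats(roi_g, masked)
  expect_equal(c(st$red_mean, st$green_mean, st$blue_mean), c(100, 80, 60))
})

test_that("mask_artifacts keeps ordinary pixel noise and is idempotent", {
  set.seed(11)
  roi <- tibble::tibble(red = 100 + rnorm(2000, 0, 5),
                        green = 80 + rnorm(2000, 0, 5),
                        blue = 60 + rnorm(2000, 0, 5))
  roi <- dplyr::mutate(roi, dplyr::across(dplyr::everything(),
                                          ~ pmin(pmax(.x, 0), 255)))
  masked <- mask_artifacts(roi)
  expect_lt(mean(masked), 0.02)

  # re-masking the survivors of the uniform + glare fixture masks nothing new
  roi_g <- dplyr::bind_rows(uniform_roi(1900, c(100, 80, 60)),
                            uniform_roi(100, c(255, 255, 255)))
  survivors <- roi_g[!mask_artifacts(roi_g), ]
  expect_equal(sum(mask_artifacts(survivors)), 0)
})

test_that("read_plate recovers manifest well means on a clean render", {
  m <- response_model()                 # default noise
  rr <- render_and_read(m, concs8, seed = 3)
  expect_equal(nrow(rr$obs), 8)
  expect_true(all(rr$obs$valid))
  expect_lt(max(abs(rr$obs$blue_mean - rr$render$manifest$wells$blue_expected)),
            1.0)
})

test_that("a fully glared well is flagged invalid and excluded", {
  m <- noiseless_model()
  layout <- well_layout(n_rows = 1, n_cols = 8)
  pm <- standards_map(concs8)
  ren <- render_plate(m, pm, layout, seed = 4)
  img <- ren$image$pixels
  ctr <- c(ren$manifest$wells$center_row[3], ren$manifest$wells$center_col[3])
  # paint 60% of the ROI area as glare around well 3's centre
  r_glare <- sqrt(0.6) * layout$roi_radius_px
  for (k in 1:3) {
    plane <- img[, , k]
    rows <- matrix(seq_len(nrow(plane)), nrow(plane), ncol(plane))
    cols <- matrix(seq_len(ncol(plane)), nrow(plane), ncol(plane),
                   byrow = TRUE)
    plane[(rows - ctr[1])^2 + (cols - ctr[2])^2 <= r_glare^2] <- 255
    img[, , k] <- plane
  }
  obs <- suppressWarnings(
    read_plate(plate_image(img), layout, pm))
  expect_false(obs$valid[3])
  expect_equal(sum(obs$valid), 7)
  expect_true(is.na(obs$blue_mean[3]))
})

test_that("plate map / layout mismatch is a configuration error", {
  m <- noiseless_model()
  layout <- well_layout(n_rows = 1, n_cols = 8)
  ren <- render_plate(m, standards_map(concs8), layout, seed = 1)
  pm9 <- standards_map(c(concs8, 31))
  expect_error(read_plate(ren$image, layout, pm9), "configuration error")
  pm_dup <- standards_map(concs8)
  pm_dup$well_id[2] <- "W01"
  expect_error(read_plate(ren$image, layout, pm_dup), "duplicated")
})

test_that("results are invariant to integer translation of the plate", {
  m <- noiseless_model()
  layout <- well_layout(n_rows = 1, n_cols = 4)
  pm <- standards_map(c(6.03, 10.07, 18.13, 30.03))
  ren <- render_plate(m, pm, layout, seed = 5)
  obs <- read_plate(ren$image, locate_wells(ren$image, layout), pm)

  shift <- c(9L, 13L)
  old <- ren$image$pixels
  big <- array(0, dim(old) + c(shift, 0L))
  for (k in 1:3) big[, , k] <- m$background[k]
  big[shift[1] + seq_len(dim(old)[1]), shift[2] + seq_len(dim(old)[2]), ] <- old
  layout2 <- well_layout(n_rows = 1, n_cols = 4,
                         first_center_px = c(60, 60) + shift,
                         image_size = dim(big)[1:2])
  img2 <- plate_image(big)
  obs2 <- read_plate(img2, locate_wells(img2, layout2), pm)
  expect_equal(obs[, -1], obs2[, -1])
})
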