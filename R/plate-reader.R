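#' Refine well centres on a plate photograph
#'
#' Starting from the regular grid in `layout`, each centre is moved to the
#' intensity-weighted centroid of `255 - brightness` (wells are darker than
#' the near-white strip material) computed over a square search window of
#' half the pitch on either side of the nominal centre. The refinement is
#' bounded to +/- 0.25 pitch so a well can never be attracted into its
#' neighbour.
#'
#' @param image A [plate_image].
#' @param layout A [well_layout] whose grid is geometrically consistent
#'   with the image (every refined ROI must stay inside it).
#' @return The layout with refined (fractional) centres.
#' @export
locate_wells <- function(image, layout) {
  stopifnot(inherits(image, "plate_image"), inherits(layout, "well_layout"))
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h != layout$image_size[1] || w != layout$image_size[2]) {
    stop("layout error: layout image_size ",
         paste(layout$image_size, collapse = " x "),
         " does not match image ", h, " x ", w, call. = FALSE)
  }
  half <- layout$pitch_px / 2
  max_shift <- 0.25 * layout$pitch_px
  refined <- purrr::pmap_dfr(layout$centers, function(well_id, row, col) {
    r0 <- max(1L, ceiling(row - half)); r1 <- min(h, floor(row + half))
    c0 <- max(1L, ceiling(col - half)); c1 <- min(w, floor(col + half))
    win <- px[r0:r1, c0:c1, , drop = FALSE]
    bright <- pmax(win[, , 1], win[, , 2], win[, , 3])
    wgt <- 255 - bright
    tot <- sum(wgt)
    if (tot <= 0) {                       # featureless window: keep the grid
      return(tibble::tibble(well_id = well_id, row = row, col = col))
    }
    rows <- matrix(r0:r1, nrow = r1 - r0 + 1, ncol = c1 - c0 + 1)
    cols <- matrix(c0:c1, nrow = r1 - r0 + 1, ncol = c1 - c0 + 1, byrow = TRUE)
    dr <- sum(wgt * rows) / tot - row
    dc <- sum(wgt * cols) / tot - col
    tibble::tibble(
      well_id = well_id,
      row = row + max(-max_shift, min(max_shift, dr)),
      col = col + max(-max_shift, min(max_shift, dc))
    )
  })
  layout$centers <- refined
  check_layout_in_image(layout)
  layout
}

#' Extract the circular ROI pixels around a centre
#'
#' @param image A [plate_image].
#' @param center Length-2 numeric `(row, col)`.
#' @param radius_px ROI radius in pixels.
#' @return A tibble with columns `row`, `col`, `red`, `green`, `blue`.
#' @export
extract_roi_pixels <- function(image, center, radius_px) {
  px <- image$pixels
  r0 <- max(1L, floor(center[1] - radius_px))
  r1 <- min(dim(px)[1], ceiling(center[1] + radius_px))
  c0 <- max(1L, floor(center[2] - radius_px))
  c1 <- min(dim(px)[2], ceiling(center[2] + radius_px))
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- (grid$row - center[1])^2 + (grid$col - center[2])^2 <= radius_px^2
  grid <- grid[keep, ]
  idx <- cbind(grid$row, grid$col)
  tibble::tibble(
    row = grid$row, col = grid$col,
    red = px[cbind(idx, 1L)],
    green = px[cbind(idx, 2L)],
    blue = px[cbind(idx, 3L)]
  )
}

#' Flag glare and bubble pixels inside an ROI
#'
#' A pixel is masked iff its brightness (max RGB) reaches
#' `glare_brightness_min`, or any of its channels deviates from that
#' channel's ROI median by more than `k_mad * 1.4826 * MAD` (the 1.4826
#' factor makes the raw median absolute deviation consistent with a
#' Gaussian sigma). A channel whose MAD is zero -- a uniform field --
#' contributes no deviation criterion, so uniform ROIs are never masked by
#' their own sharpness.
#'
#' @param pixels Data frame with `red`, `green`, `blue` columns (>= 100
#'   rows).
#' @param k_mad Robust-sigma multiplier for the deviation rule.
#' @param glare_brightness_min Brightness at or above which a pixel is
#'   treated as specular glare.
#' @return Logical vector, `TRUE` for masked pixels.
#' @export
mask_artifacts <- function(pixels, k_mad = 3.5, glare_brightness_min = 250) {
  stopifnot(is.data.frame(pixels), nrow(pixels) >= 100L)
  r <- pixels$red; g <- pixels$green; b <- pixels$blue
  glare <- pmax(r, g, b) >= glare_brightness_min
  dev_mask <- rep(FALSE, nrow(pixels))
  for (x in list(r, g, b)) {
    med <- stats::median(x)
    mad_raw <- stats::median(abs(x - med))
    if (mad_raw > 0) {
      dev_mask <- dev_mask | abs(x - med) > k_mad * 1.4826 * mad_raw
    }
  }
  glare | dev_mask
}

#' Read per-well observations from a plate photograph
#'
#' For every well in `layout`, carves the central ROI, masks glare/bubble
#' pixels, computes channel statistics and joins the plate-map annotation.
#' Wells whose masked fraction exceeds `reject_fraction` (or whose ROI
#' degenerates below 100 usable pixels) are flagged invalid with a warning
#' and must be excluded from calibration and quantification downstream.
#'
#' @param image A [plate_image].
#' @param layout A [well_layout], typically refined by [locate_wells()].
#' @param plate_map Data frame with columns `well_id`, `role`, `matrix`,
#'   `nominal_conc`, `added_conc` covering every well in the layout. Roles:
#'   `standard`, `qc`, `sample`, `spiked_sample`, `reference_standard`,
#'   `blank`.
#' @param k_mad,glare_brightness_min Passed to [mask_artifacts()].
#' @param reject_fraction Maximum tolerated masked fraction.
#' @return A tibble with one row per well: the plate-map columns, the
#'   [roi_channel_stats()] columns, `masked_fraction` and `valid`.
#' @export
read_plate <- function(image, layout, plate_map, k_mad = 3.5,
                       glare_brightness_min = 250, reject_fraction = 0.30) {
  stopifnot(inherits(image, "plate_image"), inherits(layout, "well_layout"))
  plate_map <- validate_plate_map(plate_map)
  if (!setequal(plate_map$well_id, layout$centers$well_id) ||
      nrow(plate_map) != layout$n_wells) {
    stop("configuration error: plate map wells {",
         paste(sort(plate_map$well_id), collapse = ","),
         "} do not match layout wells {",
         paste(sort(layout$centers$well_id), collapse = ","), "}",
         call. = FALSE)
  }
  obs <- purrr::pmap_dfr(layout$centers, function(well_id, row, col) {
    roi <- extract_roi_pixels(image, c(row, col), layout$roi_radius_px)
    masked <- mask_artifacts(roi, k_mad = k_mad,
                             glare_brightness_min = glare_brightness_min)
    mfrac <- mean(masked)
    valid <- mfrac <= reject_fraction && sum(!masked) >= 100L
    if (!valid) {
      warning("well ", well_id, " rejected: masked fraction ",
              sprintf("%.2f", mfrac), " exceeds limit ", reject_fraction,
              call. = FALSE)
      stats <- tibble::tibble(
        red_mean = NA_real_, green_mean = NA_real_, blue_mean = NA_real_,
        rgb_mean = NA_real_, hue_mean = NA_real_, saturation_mean = NA_real_,
        brightness_mean = NA_real_,
        n_pixels_total = nrow(roi), n_pixels_masked = sum(masked))
    } else {
      stats <- roi_channel_stats(roi, masked)
    }
    dplyr::bind_cols(tibble::tibble(well_id = well_id), stats,
                     tibble::tibble(masked_fraction = mfrac, valid = valid))
  })
  plate_map |>
    dplyr::left_join(obs, by = "well_id") |>
    tibble::as_tibble()
}

plate_roles <- function() {
  c("standard", "qc", "sample", "spiked_sample", "reference_standard", "blank")
}

validate_plate_map <- function(plate_map) {
  req <- c("well_id", "role", "matrix", "nominal_conc", "added_conc")
  missing_cols <- setdiff(req, names(plate_map))
  if (length(missing_cols)) {
    stop("plate map lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(plate_map$role), plate_roles())
  if (length(bad)) {
    stop("unknown plate-map role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(plate_map$well_id)) {
    stop("plate map contains duplicated well_id entries", call. = FALSE)
  }
  tibble::as_tibble(plate_map) |>
    dplyr::mutate(nominal_conc = as.numeric(.data$nominal_conc),
                  added_conc = as.numeric(.data$added_conc))
}

#' Read / write a plate map CSV
#'
#' The CSV carries the header
#' `well_id,role,matrix,nominal_conc,added_conc`; empty concentration cells
#' mean "not applicable" and are read as `NA`.
#'
#' @param path CSV path.
#' @param plate_map A plate-map tibble.
#' @return `read_plate_map`: a validated tibble; `write_plate_map`: `path`
#'   invisibly.
#' @export
read_plate_map <- function(path) {
  validate_plate_map(readr::read_csv(
    path,
    col_types = readr::cols(
      well_id = readr::col_character(), role = readr::col_character(),
      matrix = readr::col_character(), nominal_conc = readr::col_double(),
      added_conc = readr::col_double())
  ))
}

#' @rdname read_plate_map
#' @export
write_plate_map <- function(plate_map, path) {
  readr::write_csv(validate_plate_map(plate_map), path, na = "")
  invisible(path)
}

#' Write the per-well observation table as CSV
#'
#' @param observations Output of [read_plate()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  cols <- c("well_id", "role", "matrix", "nominal_conc", "added_conc",
            "red_mean", "green_mean", "blue_mean", "rgb_mean", "hue_mean",
            "saturation_mean", "brightness_mean", "masked_fraction", "valid")
  readr::write_csv(observations[, cols], path, na = "")
  invisible(path)
}
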