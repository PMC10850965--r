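#' Construct a plate image
#'
#' Wraps an 8-bit RGB raster (values 0-255) together with free-form capture
#' metadata (camera, lightbox, minutes since oxidant addition, ...).
#'
#' @param pixels Numeric H x W x 3 array with values in `[0, 255]`.
#' @param meta Named list of capture metadata.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, meta = list()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  d <- dim(pixels)
  if (d[1] < 64L || d[2] < 64L) {
    stop("plate image must be at least 64 x 64 pixels", call. = FALSE)
  }
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, meta = meta), class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %d x %d px, 3 channels (8-bit RGB)\n", d[1], d[2]))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                       collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a plate photograph from PNG or TIFF
#'
#' 8-bit RGB input is returned on the 0-255 scale. Higher bit depths are
#' linearly rescaled to 0-255 on load (both readers normalise to `[0, 1]`);
#' a note is emitted when the source values are not 8-bit-exact.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [plate_image].
#' @export
read_plate_image <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw01 <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(raw01)) == 3L && dim(raw01)[3] >= 3L) {
    raw01 <- raw01[, , 1:3, drop = FALSE]   # drop alpha if present
  } else {
    stop("expected an RGB image, got ", paste(dim(raw01), collapse = " x "),
         call. = FALSE)
  }
  px <- raw01 * 255
  if (max(abs(px - round(px))) > 1e-6) {
    message("note: source image is not 8-bit; values linearly rescaled to 0-255")
  }
  plate_image(px, meta = list(source = path))
}

#' Write a plate image to PNG
#'
#' @param image A [plate_image] or an H x W x 3 array on the 0-255 scale.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(image, path) {
  px <- if (inherits(image, "plate_image")) image$pixels else image
  png::writePNG(round(px) / 255, target = path)
  invisible(path)
}

#' Define the well grid and ROI geometry of a microstrip photo
#'
#' Describes where the wells sit in the image (a regular grid: first well
#' centre plus a fixed pitch) and how large the central region of interest
#' carved from each well is. The ROI must sit well inside the well so the
#' statistics avoid reflections from the strip material near the edges; the
#' default 25 px radius gives an ROI area of ~1963 square pixels, inside
#' the 1500-2200 px^2 band this assay was characterised with.
#'
#' Coordinates are 1-based `(row, col)` with the origin at the top-left,
#' matching R's array indexing.
#'
#' @param n_rows,n_cols Well grid dimensions.
#' @param pitch_px Centre-to-centre well spacing in pixels.
#' @param first_center_px Length-2 numeric, `(row, col)` of the first
#'   (top-left) well centre.
#' @param well_radius_px Radius of the rendered/physical well disc.
#' @param roi_radius_px Radius of the central ROI disc; must be smaller
#'   than `well_radius_px`.
#' @param image_size Length-2 integer `(height, width)`; defaults to a
#'   canvas that leaves one `first_center_px` margin beyond the last well.
#' @param roi_area_band Length-2 numeric; permitted ROI disc area in square
#'   pixels.
#' @return An object of class `well_layout` with a `centers` tibble
#'   (`well_id`, `row`, `col`).
#' @export
well_layout <- function(n_rows = 1L, n_cols, pitch_px = 70,
                        first_center_px = c(60, 60),
                        well_radius_px = 30, roi_radius_px = 25,
                        image_size = NULL,
                        roi_area_band = c(1500, 2200)) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_px > 0,
            length(first_center_px) == 2)
  if (roi_radius_px >= well_radius_px) {
    stop("roi_radius_px must be smaller than well_radius_px", call. = FALSE)
  }
  if (pitch_px < 2 * well_radius_px) {
    stop("wells overlap: pitch_px < 2 * well_radius_px", call. = FALSE)
  }
  roi_area <- pi * roi_radius_px^2
  if (roi_area < roi_area_band[1] || roi_area > roi_area_band[2]) {
    stop(sprintf(
      "ROI disc area %.0f px^2 outside the configured band [%g, %g]",
      roi_area, roi_area_band[1], roi_area_band[2]), call. = FALSE)
  }
  if (is.null(image_size)) {
    image_size <- c(
      ceiling(2 * first_center_px[1] + (n_rows - 1) * pitch_px),
      ceiling(2 * first_center_px[2] + (n_cols - 1) * pitch_px)
    )
  }
  grid <- expand.grid(row_i = seq_len(n_rows), col_i = seq_len(n_cols))
  grid <- grid[order(grid$row_i, grid$col_i), ]
  centers <- tibble::tibble(
    well_id = sprintf("W%02d", seq_len(nrow(grid))),
    row = first_center_px[1] + (grid$row_i - 1) * pitch_px,
    col = first_center_px[2] + (grid$col_i - 1) * pitch_px
  )
  layout <- structure(list(
    n_wells = nrow(centers),
    centers = centers,
    pitch_px = pitch_px,
    well_radius_px = well_radius_px,
    roi_radius_px = roi_radius_px,
    image_size = as.integer(image_size)
  ), class = "well_layout")
  check_layout_in_image(layout)
  layout
}

check_layout_in_image <- function(layout) {
  r <- layout$roi_radius_px
  h <- layout$image_size[1]; w <- layout$image_size[2]
  ok <- layout$centers$row - r >= 1 & layout$centers$row + r <= h &
    layout$centers$col - r >= 1 & layout$centers$col + r <= w
  if (!all(ok)) {
    stop("layout error: ROI disc(s) for ",
         paste(layout$centers$well_id[!ok], collapse = ", "),
         " fall outside the image", call. = FALSE)
  }
  invisible(layout)
}

#' @export
print.well_layout <- function(x, ...) {
  cat(sprintf(
    "<well_layout> %d wells, pitch %g px, well radius %g px, ROI radius %g px (area %.0f px^2), image %d x %d\n",
    x$n_wells, x$pitch_px, x$well_radius_px, x$roi_radius_px,
    pi * x$roi_radius_px^2, x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Write / read a well layout as YAML
#'
#' Persists grid geometry with the keys `grid.rows`, `grid.cols`,
#' `grid.pitch_px`, `grid.first_center_px`, `roi.radius_px`,
#' `well.radius_px`, `image.size`.
#'
#' @param layout A [well_layout].
#' @param path YAML file path.
#' @return `write_layout_yaml`: `path` invisibly; `read_layout_yaml`: a
#'   [well_layout].
#' @export
write_layout_yaml <- function(layout, path) {
  first <- c(layout$centers$row[1], layout$centers$col[1])
  rows <- length(unique(layout$centers$row))
  cols <- length(unique(layout$centers$col))
  yaml::write_yaml(list(
    grid = list(rows = rows, cols = cols, pitch_px = layout$pitch_px,
                first_center_px = first),
    roi = list(radius_px = layout$roi_radius_px),
    well = list(radius_px = layout$well_radius_px),
    image = list(size = as.integer(layout$image_size))
  ), path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  well_layout(
    n_rows = y$grid$rows, n_cols = y$grid$cols, pitch_px = y$grid$pitch_px,
    first_center_px = as.numeric(y$grid$first_center_px),
    well_radius_px = y$well$radius_px, roi_radius_px = y$roi$radius_px,
    image_size = as.integer(y$image$size)
  )
}
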