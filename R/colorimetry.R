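#' Convert RGB values to HSB on the 0-255 ImageJ scale
#'
#' Standard hue/saturation/value decomposition with all three outputs
#' rescaled to 0-255, matching the convention of ImageJ's HSB stack (hue
#' 0-255 corresponds to 0-360 degrees; saturation and brightness 0-255
#' instead of 0-1). Achromatic pixels (`max == min`) get hue 0; black
#' pixels get saturation 0.
#'
#' @param red,green,blue Numeric vectors of channel intensities in
#'   `[0, 255]`. Fractional values are allowed. Recycled to a common length.
#' @return A tibble with columns `hue`, `saturation`, `brightness`, one row
#'   per input pixel, all on the 0-255 scale.
#' @examples
#' rgb_to_hsb(255, 0, 0)        # pure red: hue 0, fully saturated
#' rgb_to_hsb(100, 150, 200)    # hue 210 deg -> 148.75 on the 0-255 scale
#' @export
rgb_to_hsb <- function(red, green, blue) {
  n <- max(length(red), length(green), length(blue))
  red <- rep_len(as.numeric(red), n)
  green <- rep_len(as.numeric(green), n)
  blue <- rep_len(as.numeric(blue), n)
  vals <- c(red, green, blue)
  if (anyNA(vals) || any(vals < 0 | vals > 255)) {
    stop("RGB inputs must lie in [0, 255] and contain no NA", call. = FALSE)
  }
  mx <- pmax(red, green, blue)
  mn <- pmin(red, green, blue)
  d <- mx - mn
  sat <- ifelse(mx > 0, 255 * d / mx, 0)
  # sector formula; red takes priority on ties, as in the classical algorithm
  dsafe <- ifelse(d > 0, d, 1)
  h_deg <- ifelse(
    mx == red, 60 * (((green - blue) / dsafe) %% 6),
    ifelse(mx == green, 60 * ((blue - red) / dsafe + 2),
           60 * ((red - green) / dsafe + 4))
  )
  hue <- ifelse(d > 0, h_deg, 0) * 255 / 360
  tibble::tibble(hue = hue, saturation = sat, brightness = mx)
}

#' Per-ROI channel statistics over unmasked pixels
#'
#' Computes the mean of each RGB channel, the mean RGB intensity, and the
#' per-pixel-averaged HSB channel means over the unmasked pixels of a
#' region of interest. HSB means are the means of the per-pixel hue,
#' saturation and brightness values -- each pixel is converted first and the
#' channel planes are then averaged (converting the mean RGB colour instead
#' would, e.g., report zero saturation for a half-red/half-blue field whose
#' every pixel is fully saturated).
#'
#' @param pixels A data frame with numeric columns `red`, `green`, `blue`
#'   (0-255) and optionally a logical `masked` column; masked pixels are
#'   excluded from every statistic.
#' @param masked Optional logical vector overriding `pixels$masked`.
#' @return A one-row tibble with columns `red_mean`, `green_mean`,
#'   `blue_mean`, `rgb_mean`, `hue_mean`, `saturation_mean`,
#'   `brightness_mean`, `n_pixels_total`, `n_pixels_masked`.
#' @export
roi_channel_stats <- function(pixels, masked = NULL) {
  stopifnot(is.data.frame(pixels),
            all(c("red", "green", "blue") %in% names(pixels)))
  if (is.null(masked)) {
    masked <- if ("masked" %in% names(pixels)) pixels$masked else
      rep(FALSE, nrow(pixels))
  }
  stopifnot(is.logical(masked), length(masked) == nrow(pixels))
  keep <- !masked
  if (sum(keep) < 100L) {
    stop("degenerate ROI: fewer than 100 unmasked pixels (",
         sum(keep), " remain of ", nrow(pixels), ")", call. = FALSE)
  }
  r <- pixels$red[keep]
  g <- pixels$green[keep]
  b <- pixels$blue[keep]
  hsb <- rgb_to_hsb(r, g, b)
  tibble::tibble(
    red_mean = mean(r),
    green_mean = mean(g),
    blue_mean = mean(b),
    rgb_mean = (mean(r) + mean(g) + mean(b)) / 3,
    hue_mean = mean(hsb$hue),
    saturation_mean = mean(hsb$saturation),
    brightness_mean = mean(hsb$brightness),
    n_pixels_total = nrow(pixels),
    n_pixels_masked = sum(masked)
  )
}

#' The candidate analytical channels
#'
#' Channel names understood by the calibration and quantification layers.
#' `hue` is carried in observations for diagnostics but is excluded from
#' automatic channel selection (it shows no usable linear dependence on
#' analyte concentration in this assay).
#' @return Character vector of channel names.
#' @export
dic_channels <- function() {
  c("red", "green", "blue", "rgb_mean", "hue", "saturation", "brightness")
}

# map a channel name to its observation-table column
channel_column <- function(channel) {
  channel <- match.arg(channel, dic_channels())
  if (channel %in% c("red", "green", "blue")) paste0(channel, "_mean")
  else if (channel == "rgb_mean") "rgb_mean"
  else paste0(channel, "_mean")
}
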