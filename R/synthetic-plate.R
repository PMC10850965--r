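#' Ground-truth colour response model for the simulator
#'
#' Each RGB channel responds linearly to analyte concentration,
#' `alpha_k + beta_k * c`, with the concentration clamped to a per-channel
#' linear window `[clip_lo_k, clip_hi_k]` before evaluation: below
#' `clip_lo` the response is flat, mimicking the loss of proportionality
#' between residual dye colour and analyte observed at low analyte levels,
#' and above `clip_hi` it saturates. The default parameters are the
#' characterised urea response of a methyl-red/hypochlorite-treated
#' oil-in-water emulsion: blue `128.19 - 3.009 c` (linear from
#' 2.52 % w/w), red `187.04 - 0.255 c` and green `171.90 - 0.452 c`
#' (linear from 8.1 % w/w), all up to 30.03 % w/w. HSB behaviour is
#' emergent from the rendered RGB, not separately parameterised.
#'
#' Noise has three placements chosen to reproduce how this assay behaves:
#' per-pixel Gaussian noise (averaged away by the ~2000-pixel ROI),
#' a per-well multiplicative illumination jitter, and a per-photo
#' multiplicative run gain shared by every well in the image -- the
#' component that in-photo calibration exists to cancel.
#'
#' @param blue,red,green Length-3 numeric `(alpha, beta, clip_lo)` per
#'   channel.
#' @param clip_hi Upper linear limit shared by the channels, % w/w.
#' @param pixel_noise_sd Per-pixel Gaussian noise sd, intensity units.
#' @param well_gain_sd Sd of the per-well multiplicative gain (mean 1).
#' @param run_gain_sd Sd of the per-photo multiplicative gain (mean 1).
#' @param glare_prob,bubble_prob Per-well probability of a specular glare
#'   disc / bubble ring artifact.
#' @param background Length-3 RGB of the empty strip material.
#' @param reaction_meta Metadata recorded with renders (dye and oxidant
#'   loadings; not used in the colour model).
#' @return An object of class `response_model`.
#' @export
response_model <- function(blue = c(128.19, -3.009, 2.52),
                           red = c(187.04, -0.255, 8.1),
                           green = c(171.90, -0.452, 8.1),
                           clip_hi = 30.03,
                           pixel_noise_sd = 6,
                           well_gain_sd = 0.01,
                           run_gain_sd = 0.05,
                           glare_prob = 0,
                           bubble_prob = 0,
                           background = c(248, 245, 242),
                           reaction_meta = list(methyl_red_ug_g = 22.8,
                                                naocl_mg_g = 1.51)) {
  ch <- list(red = red, green = green, blue = blue)
  for (nm in names(ch)) {
    v <- ch[[nm]]
    stopifnot(length(v) == 3, v[1] >= 0, v[1] <= 255, v[3] < clip_hi)
  }
  stopifnot(pixel_noise_sd >= 0, well_gain_sd >= 0, run_gain_sd >= 0,
            glare_prob >= 0, glare_prob <= 1, bubble_prob >= 0,
            bubble_prob <= 1)
  structure(list(
    channels = purrr::map(ch, ~ list(alpha = .x[1], beta = .x[2],
                                     clip_lo = .x[3], clip_hi = clip_hi)),
    pixel_noise_sd = pixel_noise_sd, well_gain_sd = well_gain_sd,
    run_gain_sd = run_gain_sd, glare_prob = glare_prob,
    bubble_prob = bubble_prob, background = background,
    reaction_meta = reaction_meta
  ), class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("<response_model>\n")
  for (nm in names(x$channels)) {
    p <- x$channels[[nm]]
    cat(sprintf("  %-5s signal = %.2f %+.3f c, linear %g-%g %% w/w\n",
                nm, p$alpha, p$beta, p$clip_lo, p$clip_hi))
  }
  cat(sprintf("  noise: pixel sd %g, well gain sd %g, run gain sd %g; glare p %g, bubble p %g\n",
              x$pixel_noise_sd, x$well_gain_sd, x$run_gain_sd,
              x$glare_prob, x$bubble_prob))
  invisible(x)
}

#' Noise-free expected channel signal at a concentration
#'
#' `alpha + beta * clamp(conc, clip_lo, clip_hi)`, clamped to the 0-255
#' intensity scale.
#'
#' @param model A [response_model()].
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @param conc Concentration(s), % w/w, non-negative.
#' @return Expected intensity (vectorised over `conc`).
#' @export
expected_signal <- function(model, channel, conc) {
  stopifnot(inherits(model, "response_model"), all(conc >= 0))
  channel <- match.arg(channel, c("red", "green", "blue"))
  p <- model$channels[[channel]]
  clamp(p$alpha + p$beta * clamp(conc, p$clip_lo, p$clip_hi), 0, 255)
}

#' Render a synthetic microstrip photograph
#'
#' Fills a near-white strip background, draws each well as a disc coloured
#' by the response model at that well's concentration (nominal plus any
#' spike), applies the shared run gain and a per-well gain, adds per-pixel
#' Gaussian noise inside the wells, injects glare discs / bubble rings per
#' the model's probabilities, and quantises to 8 bits. All randomness
#' flows from `seed`; identical inputs give bit-identical images.
#'
#' @param model A [response_model()].
#' @param plate_map Plate map covering every layout well; the rendered
#'   concentration of a well is `nominal_conc + added_conc` (missing
#'   treated as 0).
#' @param layout A [well_layout()].
#' @param seed Integer seed (mandatory).
#' @return A list with `image` (a [plate_image]), and `manifest`: per-well
#'   tibble (`well_id`, `role`, `true_conc`, true centre, gains, artifact
#'   flags and pre-noise expected channel means) plus the run-level draws.
#' @export
render_plate <- function(model, plate_map, layout, seed) {
  stopifnot(inherits(model, "response_model"),
            inherits(layout, "well_layout"))
  if (missing(seed) || is.null(seed)) {
    stop("render_plate requires an explicit seed", call. = FALSE)
  }
  plate_map <- validate_plate_map(plate_map)
  if (!setequal(plate_map$well_id, layout$centers$well_id)) {
    stop("plate map does not cover the layout wells", call. = FALSE)
  }
  h <- layout$image_size[1]; w <- layout$image_size[2]
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- model$background[k]

  withr::local_seed(seed)
  # gains truncated to [0.75, 1.25]: the capture protocol relies on the
  # camera's automatic brightness adjustment, which corrects exposure
  # outside a window around the metering target, keeping the brightest
  # content below specular clipping and the darkest quantifiable
  run_gain <- clamp(stats::rnorm(1, 1, model$run_gain_sd), 0.75, 1.25)

  rows_m <- matrix(seq_len(h), h, w)
  cols_m <- matrix(seq_len(w), h, w, byrow = TRUE)
  map_ord <- plate_map[match(layout$centers$well_id, plate_map$well_id), ]

  wells <- purrr::pmap_dfr(
    list(layout$centers$well_id, layout$centers$row, layout$centers$col,
         map_ord$role, map_ord$nominal_conc, map_ord$added_conc),
    function(well_id, cr, cc, role, nominal, added) {
      conc <- (if (is.na(nominal)) 0 else nominal) +
        (if (is.na(added)) 0 else added)
      well_gain <- clamp(stats::rnorm(1, 1, model$well_gain_sd), 0.75, 1.25)
      glare <- stats::runif(1) < model$glare_prob
      bubble <- stats::runif(1) < model$bubble_prob
      # artifact geometry drawn unconditionally to keep the RNG stream
      # aligned across probability settings
      g_off <- stats::runif(2, -0.4, 0.4) * layout$roi_radius_px
      b_r <- stats::runif(1, 0.35, 0.6) * layout$roi_radius_px
      d2 <- (rows_m - cr)^2 + (cols_m - cc)^2
      disc <- d2 <= layout$well_radius_px^2
      n_px <- sum(disc)
      expected <- purrr::map_dbl(c("red", "green", "blue"), function(ch)
        clamp(expected_signal(model, ch, conc) * run_gain * well_gain, 0, 255))
      for (k in 1:3) {
        vals <- rep(expected[k], n_px)
        if (model$pixel_noise_sd > 0) {
          vals <- vals + stats::rnorm(n_px, 0, model$pixel_noise_sd)
        }
        plane <- img[, , k]
        plane[disc] <- clamp(vals, 0, 255)
        img[, , k] <<- plane
      }
      if (bubble) {
        ring <- d2 >= (b_r - 1.5)^2 & d2 <= (b_r + 1.5)^2
        for (k in 1:3) {
          plane <- img[, , k]
          plane[ring] <- plane[ring] * 0.5
          img[, , k] <<- plane
        }
      }
      if (glare) {
        gd2 <- (rows_m - (cr + g_off[1]))^2 + (cols_m - (cc + g_off[2]))^2
        gdisc <- gd2 <= (0.25 * layout$roi_radius_px)^2
        for (k in 1:3) {
          plane <- img[, , k]
          plane[gdisc] <- 255
          img[, , k] <<- plane
        }
      }
      tibble::tibble(
        well_id = well_id, role = role, true_conc = conc,
        center_row = cr, center_col = cc, well_gain = well_gain,
        glare = glare, bubble = bubble,
        red_expected = expected[1], green_expected = expected[2],
        blue_expected = expected[3])
    })
  img <- round(img)
  list(
    image = plate_image(img, meta = list(simulated = TRUE, seed = seed,
                                         run_gain = run_gain)),
    manifest = list(wells = wells,
                    run = list(run_gain = run_gain, seed = seed))
  )
}

table3_qc_levels <- function() c(6.03, 10.07, 18.13, 23.32, 27.21, 30.03)
default_standard_levels <- function() {
  c(2.52, 6.03, 10.07, 18.13, 23.32, 27.21, 30.03)
}

#' Simulate a multi-run validation study
#'
#' Generates `n_runs` independent photographs, each containing its own
#' calibration standards plus one QC well per requested level, with a
#' fresh run-level illumination gain per photo. Writes the images (PNG),
#' plate maps (CSV), per-run manifests (JSON), the shared layout (YAML)
#' and a study index `study.csv` into `dir`, ready for the full pipeline.
#'
#' @param model A [response_model()].
#' @param levels QC concentrations, % w/w, each within the model's linear
#'   window.
#' @param n_runs Number of independent runs (photos).
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; each run renders from a derived child
#'   seed.
#' @param standard_levels In-photo calibration standards, % w/w.
#' @param matrix Matrix label written to the plate maps.
#' @return The study index tibble (`run_id`, `image`, `plate_map`,
#'   `manifest`, `layout`), invisibly.
#' @export
simulate_validation_study <- function(model, levels, n_runs, dir, seed,
                                      standard_levels = default_standard_levels(),
                                      matrix = "cream B") {
  stopifnot(inherits(model, "response_model"), n_runs >= 1)
  hi <- model$channels$blue$clip_hi
  if (any(levels <= 0 | levels > hi)) {
    stop("QC levels must lie in (0, ", hi, "] % w/w", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_wells <- length(standard_levels) + length(levels)
  layout <- well_layout(n_rows = 1L, n_cols = n_wells)
  write_layout_yaml(layout, file.path(dir, "layout.yaml"))
  plate_map <- tibble::tibble(
    well_id = sprintf("W%02d", seq_len(n_wells)),
    role = c(rep("standard", length(standard_levels)),
             rep("qc", length(levels))),
    matrix = matrix,
    nominal_conc = c(standard_levels, levels),
    added_conc = NA_real_)
  index <- purrr::map_dfr(seq_len(n_runs), function(i) {
    run_id <- sprintf("run%02d", i)
    ren <- render_plate(model, plate_map, layout, seed = child_seed(seed, i))
    img_path <- file.path(dir, paste0(run_id, ".png"))
    map_path <- file.path(dir, paste0(run_id, "_map.csv"))
    man_path <- file.path(dir, paste0(run_id, "_manifest.json"))
    write_plate_image(ren$image, img_path)
    write_plate_map(plate_map, map_path)
    jsonlite::write_json(ren$manifest, man_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    tibble::tibble(run_id = run_id, image = basename(img_path),
                   plate_map = basename(map_path),
                   manifest = basename(man_path), layout = "layout.yaml")
  })
  readr::write_csv(index, file.path(dir, "study.csv"))
  invisible(index)
}
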