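#' Acquisition grid
#'
#' The pixel grid of the synthetic camera: a rectangular field of view in
#' physical coordinates sampled at \code{um_per_px}. Pixel (row i, col j)
#' has its center at \code{x = x0 + (j - 0.5) * um_per_px},
#' \code{y = y1 - (i - 0.5) * um_per_px} (row 1 at the top, the upper
#' channel side). Both the renderer and the grid-based ground-truth
#' scorer use this object, so the two paths sample space identically.
#'
#' @param geom a \code{chip_geometry}; sets the default field of view
#'   (the active window in x; from just below the central channel floor
#'   to half a channel width above the posts in y — invasion at the
#'   simulated scales never leaves this frame).
#' @param um_per_px pixel size, um (default 1).
#' @param region optional \code{c(x0, x1, y0, y1)} field of view, um.
#' @return Object of class \code{acquisition_grid}: region, um_per_px,
#'   width_px, height_px, and the matching \code{\link{calibration}}.
#' @export
acquisition_grid <- function(geom, um_per_px = 1, region = NULL) {
  stopifnot(inherits(geom, "chip_geometry"), um_per_px > 0)
  if (is.null(region)) {
    r <- geom$post_diameter_um / 2
    region <- c(geom$active_window_x_um[1], geom$active_window_x_um[2],
                -(r + geom$channel_width_um) - 5,
                r + geom$channel_width_um / 2)
  }
  stopifnot(length(region) == 4, region[2] > region[1], region[4] > region[3])
  w <- ceiling((region[2] - region[1]) / um_per_px)
  h <- ceiling((region[4] - region[3]) / um_per_px)
  cal <- calibration(um_per_px,
                     origin_px = c(0.5 - region[1] / um_per_px,
                                   0.5 + region[4] / um_per_px),
                     y_toward_upper = TRUE)
  structure(list(region = region, um_per_px = um_per_px,
                 width_px = as.integer(w), height_px = as.integer(h),
                 calibration = cal),
            class = "acquisition_grid")
}

#' Effective thresholded blob radius
#'
#' Radius at which a Gaussian blob of the given peak falls to the
#' threshold: \code{sigma * sqrt(2 * log(peak / (thr - background)))}
#' inverted for the threshold level. This is the footprint radius a
#' noise-free segmentation recovers, and the disc radius the ground-truth
#' scorer uses.
#'
#' @param psf_sigma_um blob Gaussian sigma, um.
#' @param rel_threshold threshold as a fraction of blob peak above
#'   background (default 0.5).
#' @return Radius in um.
#' @export
effective_blob_radius <- function(psf_sigma_um, rel_threshold = 0.5) {
  stopifnot(psf_sigma_um > 0, rel_threshold > 0, rel_threshold < 1)
  psf_sigma_um * sqrt(-2 * log(rel_threshold))
}

#' Render a simulation state as a microscopy frame
#'
#' Draws each (labeled) cell as a Gaussian blob at its position on the
#' acquisition grid, adds a constant background and white Gaussian noise
#' at the stated signal-to-noise ratio (\code{snr = peak / noise SD}),
#' and quantizes to the bit depth. Fluorescence frames show only the
#' labeled subset of cells (bright on dark); brightfield frames show
#' every cell (dark on bright). Uses the caller's RNG state: seed before
#' calling for reproducibility.
#'
#' @param state a \code{sim_state} from \code{\link{simulate_chip}}.
#' @param grid an \code{\link{acquisition_grid}} (default: grid of the
#'   state's geometry at 1 um/px).
#' @param psf_sigma_um blob sigma, um (default 4: a ~10 um cell body
#'   blurred by the point-spread function).
#' @param snr peak signal-to-noise ratio (default 20).
#' @param labeled_fraction fraction of cells carrying the fluorescent
#'   label (default 1); the labeled subset is drawn without replacement.
#' @param modality \code{"fluorescence"} or \code{"brightfield"}.
#' @param peak blob peak amplitude above background, counts (default 1000).
#' @param background background level, counts (default 100).
#' @param bits_per_sample image bit depth, 8 or 16 (default 16).
#' @return List: \code{image} (a calibrated \code{\link{chip_image}}),
#'   \code{truth} (data.frame x_um, y_um, labeled for every cell),
#'   \code{grid}, \code{threshold} (the nominal half-peak threshold on
#'   the image scale) and \code{effective_radius_um}.
#' @export
render_state <- function(state, grid = NULL, psf_sigma_um = 4, snr = 20,
                         labeled_fraction = 1,
                         modality = c("fluorescence", "brightfield"),
                         peak = 1000, background = 100,
                         bits_per_sample = 16) {
  stopifnot(inherits(state, "sim_state"), snr > 0,
            labeled_fraction > 0, labeled_fraction <= 1,
            peak > 0, background >= 0)
  modality <- match.arg(modality)
  if (is.null(grid)) grid <- acquisition_grid(state$geometry)
  n <- nrow(state$positions)
  labeled <- rep(TRUE, n)
  if (labeled_fraction < 1)
    labeled <- seq_len(n) %in% sample.int(n, round(labeled_fraction * n))
  drawn <- if (modality == "fluorescence") which(labeled) else seq_len(n)
  img <- matrix(0, grid$height_px, grid$width_px)
  if (length(drawn) > 0) {
    centers_px <- to_pixel(grid$calibration,
                           state$positions[drawn, , drop = FALSE])
    .add_gaussian_blobs(img, centers_px, psf_sigma_um / grid$um_per_px,
                        peak)
  }
  maxval <- 2^bits_per_sample - 1
  if (modality == "fluorescence") {
    .finalize_image(img, 1, background, peak / snr, maxval)
    threshold <- background + peak / 2
  } else {
    # bright field: blobs absorb light from a white background
    .finalize_image(img, -1, background + 2 * peak, peak / snr, maxval)
    threshold <- peak / 2            # on the inverted, flattened scale
  }
  list(image = chip_image(img, modality = modality, day = state$day,
                          calibration = grid$calibration),
       truth = data.frame(x_um = state$positions[, 1],
                          y_um = state$positions[, 2],
                          labeled = labeled),
       grid = grid,
       threshold = threshold,
       effective_radius_um = effective_blob_radius(psf_sigma_um))
}
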