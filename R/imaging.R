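#' Construct a chip image
#'
#' A single calibrated grayscale microscopy frame of a chip channel.
#'
#' @param pixels numeric matrix of non-negative finite intensities,
#'   oriented with row 1 at the top of the frame.
#' @param modality \code{"fluorescence"} or \code{"brightfield"}.
#' @param day imaging day (integer; day 0 is chip setup).
#' @param chip_id chip identifier.
#' @param calibration a \code{\link{calibration}} object; required before
#'   any scoring.
#' @return An object of class \code{chip_image}.
#' @export
chip_image <- function(pixels, modality = c("fluorescence", "brightfield"),
                       day = NA_integer_, chip_id = NA_character_,
                       calibration = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) == Inf)
    stop("pixel intensities must be finite and non-negative")
  if (!is.null(calibration) && !inherits(calibration, "chip_calibration"))
    stop("calibration must be a chip_calibration object")
  structure(list(pixels = pixels, modality = modality,
                 day = as.integer(day), chip_id = chip_id,
                 calibration = calibration),
            class = "chip_image")
}

#' @export
print.chip_image <- function(x, ...) {
  cat("chip_image:", x$modality, "frame", ncol(x$pixels), "x",
      nrow(x$pixels), "px, chip", x$chip_id, "day", x$day, "\n")
  invisible(x)
}

#' Read a TIFF stack into chip images
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param metadata a list with \code{modality}, \code{chip_id},
#'   \code{calibration} (required) and \code{day} (scalar, or one value
#'   per page).
#' @return List of \code{\link{chip_image}}, one per page, page order
#'   preserved.
#' @export
read_image_stack <- function(path, metadata) {
  if (is.null(metadata$calibration))
    stop("config error: metadata must supply a calibration")
  pages <- read_tiff(path)
  day <- metadata$day %||% NA_integer_
  if (length(day) == 1) day <- rep(day, length(pages))
  if (length(day) != length(pages))
    stop("config error: metadata$day must be scalar or one value per page")
  lapply(seq_along(pages), function(i)
    chip_image(pages[[i]],
               modality = metadata$modality %||% "fluorescence",
               day = day[i],
               chip_id = metadata$chip_id %||% NA_character_,
               calibration = metadata$calibration))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold
#'
#' Classical between-class-variance-maximizing threshold on a 256-bin
#' histogram of the intensity range.
#'
#' @param x numeric vector or matrix of intensities.
#' @return The threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  nb <- 256
  bin <- pmin(nb, floor((v - lo) / (hi - lo) * nb) + 1)
  h <- as.numeric(tabulate(bin, nbins = nb))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nb))
  n <- w[nb]; mu_t <- mu[nb]
  wb <- w[-nb]; wf <- n - wb
  valid <- wb > 0 & wf > 0
  between <- rep(-Inf, nb - 1)
  between[valid] <- (mu_t * wb[valid] - n * mu[-nb][valid])^2 /
    (wb[valid] * wf[valid])
  k <- which.max(between)
  lo + k / nb * (hi - lo)
}

resolve_threshold <- function(work, threshold_method) {
  if (is.numeric(threshold_method)) return(threshold_method)
  if (identical(threshold_method, "otsu")) return(otsu_threshold(work))
  if (is.character(threshold_method) &&
      grepl("^fixed:", threshold_method)) {
    thr <- suppressWarnings(as.numeric(sub("^fixed:", "", threshold_method)))
    if (is.na(thr)) stop("bad fixed threshold spec: ", threshold_method)
    return(thr)
  }
  stop("threshold_method must be \"otsu\", \"fixed:<value>\" or a number")
}

#' Segment labeled cells in a chip image
#'
#' Thresholds the frame and extracts 4-connected components as cell
#' detections. Fluorescence frames are thresholded directly. Brightfield
#' frames (cells dark on a bright, dusty background) are inverted and
#' background-flattened (median subtraction) first, so the same
#' bright-foreground rule applies; a fixed threshold for brightfield is
#' therefore specified on the inverted, flattened scale. Touching cells
#' are deliberately not split: both invasion metrics (any-cell window
#' crossing, furthest pixel) are insensitive to under-segmentation.
#'
#' @param img a calibrated \code{\link{chip_image}}.
#' @param min_area_um2 minimum component area, um^2 (default 50,
#'   roughly the cross-section of an 8 um cell; excludes debris).
#' @param threshold_method \code{"otsu"} (default), \code{"fixed:<value>"},
#'   or a number.
#' @return List of \code{cell_detection} objects, sorted by descending y
#'   of each detection's furthest (most-invaded) pixel. Each has
#'   \code{centroid_um}, \code{footprint_px} (n x 2, columns x_px/y_px),
#'   \code{footprint_um}, \code{area_um2} and \code{modality}. A blank
#'   frame yields an empty list; a saturated uniform frame yields an
#'   empty list with a warning.
#' @export
segment_cells <- function(img, min_area_um2 = 50, threshold_method = "otsu") {
  stopifnot(inherits(img, "chip_image"))
  if (is.null(img$calibration))
    stop("image must be calibrated before segmentation")
  px <- img$pixels
  if (max(px) == min(px)) {
    if (max(px) > 0)
      warning("saturated uniform image: no cells segmented")
    return(list())
  }
  work <- if (img$modality == "brightfield") {
    inv <- max(px) - px
    pmax(inv - stats::median(inv), 0)
  } else px
  dim(work) <- dim(px)
  thr <- resolve_threshold(work, threshold_method)
  mask <- work > thr
  if (!any(mask)) return(list())
  lab <- .label_components(mask)
  u <- img$calibration$um_per_px
  min_px <- max(1L, ceiling(min_area_um2 / u^2))
  idx <- which(lab > 0)
  groups <- split(idx, lab[idx])
  groups <- groups[lengths(groups) >= min_px]
  if (length(groups) == 0) return(list())
  nr <- nrow(px)
  dets <- lapply(groups, function(ii) {
    r <- ((ii - 1) %% nr) + 1
    c <- ((ii - 1) %/% nr) + 1
    fp_px <- cbind(x_px = c, y_px = r)
    fp_um <- to_physical(img$calibration, fp_px)
    structure(list(
      centroid_um = colMeans(fp_um),
      footprint_px = fp_px,
      footprint_um = fp_um,
      area_um2 = nrow(fp_px) * u^2,
      modality = img$modality
    ), class = "cell_detection")
  })
  furthest <- vapply(dets, function(d) max(d$footprint_um[, 2]), numeric(1))
  unname(dets[order(furthest, decreasing = TRUE)])
}

#' Fluorescence labeling positivity rate
#'
#' Fraction of brightfield-detected cells that carry a fluorescence
#' label, estimated by greedy nearest-first centroid matching: the
#' globally closest brightfield/fluorescence pair within
#' \code{match_radius_um} is matched first, both detections are removed,
#' and the process repeats; each fluorescence detection is used at most
#' once.
#'
#' @param brightfield_dets detections from the brightfield frame.
#' @param fluorescence_dets detections from the fluorescence frame of the
#'   same field of view.
#' @param match_radius_um maximum centroid distance for a match, um
#'   (default 15, about one cell diameter).
#' @return Fraction in \code{[0, 1]}.
#' @export
positivity_rate <- function(brightfield_dets, fluorescence_dets,
                            match_radius_um = 15) {
  if (length(brightfield_dets) == 0)
    stop("positivity rate undefined: no brightfield detections")
  if (!is.finite(match_radius_um) || match_radius_um <= 0)
    stop("match_radius_um must be positive")
  if (length(fluorescence_dets) == 0) return(0)
  bf <- t(vapply(brightfield_dets, function(d) d$centroid_um, numeric(2)))
  fl <- t(vapply(fluorescence_dets, function(d) d$centroid_um, numeric(2)))
  d2 <- outer(bf[, 1], fl[, 1], "-")^2 + outer(bf[, 2], fl[, 2], "-")^2
  lim <- match_radius_um^2
  matched <- 0L
  for (k in seq_len(min(nrow(bf), nrow(fl)))) {
    m <- which.min(d2)
    if (d2[m] > lim) break
    matched <- matched + 1L
    i <- ((m - 1) %% nrow(d2)) + 1
    j <- ((m - 1) %/% nrow(d2)) + 1
    d2[i, ] <- Inf
    d2[, j] <- Inf
  }
  matched / nrow(bf)
}

#' Detections as a data frame
#'
#' @param dets list of \code{cell_detection}.
#' @param chip_id,day metadata columns to attach.
#' @return data.frame with columns chip_id, day, modality, centroid_x_um,
#'   centroid_y_um, area_um2.
#' @export
detections_to_df <- function(dets, chip_id = NA_character_,
                             day = NA_integer_) {
  if (length(dets) == 0)
    return(data.frame(chip_id = character(), day = integer(),
                      modality = character(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), area_um2 = numeric()))
  data.frame(
    chip_id = chip_id, day = day,
    modality = vapply(dets, function(d) d$modality, character(1)),
    centroid_x_um = vapply(dets, function(d) d$centroid_um[[1]], numeric(1)),
    centroid_y_um = vapply(dets, function(d) d$centroid_um[[2]], numeric(1)),
    area_um2 = vapply(dets, function(d) d$area_um2, numeric(1))
  )
}
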