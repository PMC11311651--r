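#' Build a parametric chip geometry
#'
#' Models the physical layout of one post row of the microfluidic chip in
#' micrometre coordinates, together with the scoring geometry: the
#' inter-post threshold (IPT) windows and the two reference lines used by
#' the invasion metrics.
#'
#' The coordinate frame has its origin at the left end of the post row, on
#' the post-center line, with +y pointing toward the upper Matrigel
#' channel. A row of \code{n_posts} posts creates \code{n_posts + 1} IPT
#' windows. Vertical window boundaries sit at post-center x coordinates;
#' the first and last windows are closed by the edges of the active window
#' (the x extent containing posts and gaps). The horizontal crossing
#' boundary sits at the post outer edge on the Matrigel side,
#' \code{post_diameter_um / 2} above the post-center line, while invasion
#' distance is measured from the post-center line itself; the two lines
#' are kept distinct because the assay defines them differently.
#'
#' The posts occupy an active window of length
#' \code{n_posts * post_diameter_um + (n_posts + 1) * post_gap_um}
#' (5.8 mm for the defaults), centered along the channel; the remainder of
#' the channel length carries no scoring geometry.
#'
#' @param n_posts number of posts in the divider row (default 16).
#' @param post_diameter_um post diameter, um (default 150).
#' @param post_gap_um edge-to-edge gap between adjacent posts, um
#'   (default 200).
#' @param channel_width_um width of one channel, um (default 1000).
#' @param channel_length_um channel length, um (default 30000).
#' @return An object of class \code{chip_geometry}: a list with the input
#'   dimensions plus \code{post_centers_x_um}, \code{post_center_y_um}
#'   (always 0), \code{active_window_x_um} (length-2), \code{ipt_windows}
#'   (an (n_posts+1) x 2 matrix of half-open \code{[lo, hi)} x intervals),
#'   and \code{crossing_boundary_y_um}.
#' @examples
#' geom <- build_geometry()
#' nrow(geom$ipt_windows)        # 17
#' geom$crossing_boundary_y_um   # 75
#' @export
build_geometry <- function(n_posts = 16, post_diameter_um = 150,
                           post_gap_um = 200, channel_width_um = 1000,
                           channel_length_um = 30000) {
  stopifnot(length(n_posts) == 1, length(post_diameter_um) == 1,
            length(post_gap_um) == 1, length(channel_width_um) == 1,
            length(channel_length_um) == 1)
  if (n_posts < 1 || n_posts != round(n_posts))
    stop("n_posts must be a positive integer")
  dims <- c(post_diameter_um, post_gap_um, channel_width_um,
            channel_length_um)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all dimensions must be positive and finite")
  active_len <- n_posts * post_diameter_um + (n_posts + 1) * post_gap_um
  if (active_len > channel_length_um)
    stop("posts do not fit in channel: active window ", active_len,
         " um exceeds channel length ", channel_length_um, " um")
  pitch <- post_diameter_um + post_gap_um
  centers <- post_gap_um + post_diameter_um / 2 + (seq_len(n_posts) - 1) * pitch
  bounds <- c(0, centers, active_len)
  windows <- cbind(lo = bounds[-length(bounds)], hi = bounds[-1])
  structure(list(
    n_posts = as.integer(n_posts),
    post_diameter_um = post_diameter_um,
    post_gap_um = post_gap_um,
    channel_width_um = channel_width_um,
    channel_length_um = channel_length_um,
    post_centers_x_um = centers,
    post_center_y_um = 0,
    active_window_x_um = c(0, active_len),
    ipt_windows = windows,
    crossing_boundary_y_um = post_diameter_um / 2
  ), class = "chip_geometry")
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat("chip_geometry:", x$n_posts, "posts (",
      x$post_diameter_um, "um diameter,", x$post_gap_um, "um gap ),",
      nrow(x$ipt_windows), "IPT windows\n")
  cat("  active window x: [", x$active_window_x_um[1], ",",
      x$active_window_x_um[2], ") um; crossing boundary y =",
      x$crossing_boundary_y_um, "um\n")
  invisible(x)
}

#' Look up one IPT window
#'
#' @param geometry a \code{chip_geometry}.
#' @param index window index, 1-based, in \code{1..(n_posts+1)}.
#' @return Numeric length-2 vector \code{c(lo, hi)}; the interval is
#'   half-open \code{[lo, hi)} so a point on a post-center boundary
#'   belongs to exactly one window.
#' @export
ipt_window <- function(geometry, index) {
  stopifnot(inherits(geometry, "chip_geometry"))
  n <- nrow(geometry$ipt_windows)
  if (length(index) != 1 || index != round(index) || index < 1 || index > n)
    stop("window index out of range 1..", n)
  geometry$ipt_windows[index, ]
}

#' Assign x coordinates to IPT windows
#'
#' Uses the half-open convention: a coordinate exactly on a post-center
#' boundary belongs to the window on its right.
#'
#' @param geometry a \code{chip_geometry}.
#' @param x numeric vector of physical x coordinates, um.
#' @return Integer vector of window indices (1-based); NA for
#'   coordinates outside the active window.
#' @export
ipt_window_of <- function(geometry, x) {
  stopifnot(inherits(geometry, "chip_geometry"))
  bounds <- c(geometry$ipt_windows[, "lo"],
              geometry$ipt_windows[nrow(geometry$ipt_windows), "hi"])
  idx <- findInterval(x, bounds, left.open = FALSE, rightmost.closed = FALSE)
  idx[idx < 1 | idx > nrow(geometry$ipt_windows)] <- NA_integer_
  as.integer(idx)
}

#' Image calibration
#'
#' Affine map between pixel and physical micrometre coordinates. Pixel
#' coordinates are \code{(x_px, y_px)} = (column, row). With
#' \code{y_toward_upper = TRUE} (the default, matching the usual image
#' orientation with the upper Matrigel channel at the top of the frame),
#' increasing row number means decreasing physical y.
#'
#' @param um_per_px micrometres per pixel, > 0 (default 1).
#' @param origin_px pixel coordinates \code{c(x_px, y_px)} that map to the
#'   physical origin (default \code{c(0, 0)}).
#' @param y_toward_upper logical; TRUE if the top of the image is the
#'   upper channel side.
#' @return An object of class \code{chip_calibration}.
#' @export
calibration <- function(um_per_px = 1, origin_px = c(0, 0),
                        y_toward_upper = TRUE) {
  if (!is.finite(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be positive")
  stopifnot(length(origin_px) == 2, all(is.finite(origin_px)))
  structure(list(um_per_px = um_per_px,
                 origin_px = as.numeric(origin_px),
                 y_toward_upper = isTRUE(y_toward_upper)),
            class = "chip_calibration")
}

#' Convert pixel coordinates to physical micrometres
#'
#' @param cal a \code{chip_calibration}.
#' @param px numeric vector \code{c(x_px, y_px)} or an n x 2 matrix.
#' @return Same shape as \code{px}, in um.
#' @export
to_physical <- function(cal, px) {
  stopifnot(inherits(cal, "chip_calibration"))
  p <- if (is.matrix(px)) px else matrix(px, ncol = 2)
  sgn <- if (cal$y_toward_upper) -1 else 1
  out <- cbind((p[, 1] - cal$origin_px[1]) * cal$um_per_px,
               sgn * (p[, 2] - cal$origin_px[2]) * cal$um_per_px)
  colnames(out) <- c("x_um", "y_um")
  if (is.matrix(px)) out else drop(out)
}

#' Convert physical micrometres to pixel coordinates
#'
#' Exact inverse of \code{\link{to_physical}} (continuous, not rounded).
#'
#' @param cal a \code{chip_calibration}.
#' @param um numeric vector \code{c(x_um, y_um)} or an n x 2 matrix.
#' @return Same shape as \code{um}, in pixels.
#' @export
to_pixel <- function(cal, um) {
  stopifnot(inherits(cal, "chip_calibration"))
  p <- if (is.matrix(um)) um else matrix(um, ncol = 2)
  sgn <- if (cal$y_toward_upper) -1 else 1
  out <- cbind(p[, 1] / cal$um_per_px + cal$origin_px[1],
               sgn * p[, 2] / cal$um_per_px + cal$origin_px[2])
  colnames(out) <- c("x_px", "y_px")
  if (is.matrix(um)) out else drop(out)
}

#' Export a chip geometry as JSON
#'
#' For provenance alongside score tables.
#'
#' @param geometry a \code{chip_geometry}.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
geometry_json <- function(geometry, path = NULL) {
  stopifnot(inherits(geometry, "chip_geometry"))
  g <- unclass(geometry)
  g$ipt_windows <- apply(geometry$ipt_windows, 1,
                         function(w) list(lo = w[[1]], hi = w[[2]]),
                         simplify = FALSE)
  js <- jsonlite::toJSON(g, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
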