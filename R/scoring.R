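#' Score IPT crossings from cell detections
#'
#' An inter-post threshold (IPT) window is marked crossed when at least
#' one detection has at least one footprint pixel beyond the crossing
#' boundary (the post outer edge on the Matrigel side) with x inside the
#' window. A cell spanning several windows marks every window in which it
#' has crossing pixels. Judgment is on the pixel footprint, not the
#' centroid: invading cells extend processes past the posts well before
#' their centroid follows, and those count as crossings in the assay.
#'
#' @param dets list of \code{cell_detection} in physical um coordinates
#'   consistent with \code{geom}.
#' @param geom a \code{\link{build_geometry}} result.
#' @return Logical vector with one entry per IPT window (17 for default
#'   geometry); all FALSE for an empty detection list.
#' @export
score_crossings <- function(dets, geom) {
  stopifnot(inherits(geom, "chip_geometry"))
  out <- rep(FALSE, nrow(geom$ipt_windows))
  for (d in dets) {
    fp <- d$footprint_um
    over <- fp[, 2] > geom$crossing_boundary_y_um
    if (!any(over)) next
    w <- ipt_window_of(geom, fp[over, 1])
    out[unique(w[!is.na(w)])] <- TRUE
  }
  out
}

#' Count IPTs crossed
#'
#' @param crossings logical crossing vector.
#' @param n_windows expected number of windows (default 17, the full post
#'   row of the standard chip).
#' @return Integer number of crossed windows.
#' @export
count_ipts <- function(crossings, n_windows = 17) {
  if (!is.logical(crossings) || anyNA(crossings))
    stop("crossings must be a logical vector without NAs")
  if (length(crossings) != n_windows)
    stop("crossing vector has length ", length(crossings),
         ", expected ", n_windows)
  sum(crossings)
}

#' Maximum invasion distance
#'
#' The furthest extent of any detection's footprint beyond the
#' post-center line, measured perpendicular to the post row. Note the
#' asymmetry with \code{\link{score_crossings}}: crossing is judged at
#' the post OUTER edge, but distance is measured from the post CENTER
#' line — the assay defines the two reference lines differently, and they
#' differ by half a post diameter (75 um for defaults). Cells that have
#' not passed the center line score 0 (never negative).
#'
#' @param dets list of \code{cell_detection}.
#' @param geom a \code{chip_geometry}.
#' @return Distance in um (>= 0); 0 for an empty list.
#' @export
max_invasion_distance <- function(dets, geom) {
  stopifnot(inherits(geom, "chip_geometry"))
  if (length(dets) == 0) return(0)
  ys <- vapply(dets, function(d) max(d$footprint_um[, 2]), numeric(1))
  max(0, max(ys) - geom$post_center_y_um)
}

#' Score one chip image's detections
#'
#' Bundles the two invasion metrics into an \code{invasion_score} record
#' and logs a diagnostic count of detections invading downward into the
#' lower Matrigel channel (a rare event in the assay; it is counted but
#' never scored).
#'
#' @param dets detections in physical um coordinates.
#' @param geom a \code{chip_geometry}.
#' @param chip_id,day record metadata.
#' @param dose_uM,cell_line optional treatment metadata carried through to
#'   tables.
#' @return An \code{invasion_score}: chip_id, day, crossings (logical
#'   vector), n_ipts_crossed, max_distance_um, n_downward, dose_uM,
#'   cell_line.
#' @export
score_chip <- function(dets, geom, chip_id = NA_character_,
                       day = NA_integer_, dose_uM = NA_real_,
                       cell_line = NA_character_) {
  crossings <- score_crossings(dets, geom)
  lower_edge <- geom$post_center_y_um - geom$post_diameter_um / 2
  n_down <- sum(vapply(dets, function(d)
    any(d$footprint_um[, 2] < lower_edge), logical(1)))
  if (n_down > 0)
    message("chip ", chip_id, " day ", day, ": ", n_down,
            " detection(s) past the lower post edge (not scored)")
  structure(list(
    chip_id = chip_id, day = as.integer(day),
    crossings = crossings,
    n_ipts_crossed = count_ipts(crossings, nrow(geom$ipt_windows)),
    max_distance_um = max_invasion_distance(dets, geom),
    n_downward = n_down,
    dose_uM = dose_uM, cell_line = cell_line
  ), class = "invasion_score")
}

#' @export
print.invasion_score <- function(x, ...) {
  cat("invasion_score: chip", x$chip_id, "day", x$day, "-",
      x$n_ipts_crossed, "/", length(x$crossings), "IPTs crossed,",
      "max distance", round(x$max_distance_um, 1), "um\n")
  invisible(x)
}

#' Ground-truth scoring from agent coordinates
#'
#' Scores simulated cell positions directly, bypassing rendering, noise
#' and segmentation, for closed-loop validation. Each agent is treated as
#' a disc of radius \code{cell_radius_um} — the physical extent the
#' renderer draws and the segmenter recovers; with the default 0 the
#' agents are scored as points.
#'
#' With \code{grid = NULL} the discs are continuous. When a \code{grid}
#' (from \code{\link{acquisition_grid}}) is supplied, each disc is
#' discretized to the pixel centers of the stated acquisition grid before
#' scoring, so the truth and a noise-free imaging measurement agree
#' exactly: a sub-pixel sliver of a disc that no pixel center samples is
#' not scored by either path. Agents outside the grid's field of view are
#' not scored (matching what the camera would see).
#'
#' @param positions n x 2 matrix of (x_um, y_um) agent positions.
#' @param geom a \code{chip_geometry}.
#' @param cell_radius_um effective cell radius, um.
#' @param grid optional \code{\link{acquisition_grid}}.
#' @return List with \code{crossings}, \code{n_ipts_crossed} and
#'   \code{max_distance_um}, defined exactly as for detections.
#' @export
score_positions <- function(positions, geom, cell_radius_um = 0,
                            grid = NULL) {
  stopifnot(inherits(geom, "chip_geometry"), is.matrix(positions),
            ncol(positions) == 2, cell_radius_um >= 0)
  if (!is.null(grid)) return(score_positions_grid(positions, geom,
                                                  cell_radius_um, grid))
  r <- cell_radius_um
  yb <- geom$crossing_boundary_y_um
  crossings <- rep(FALSE, nrow(geom$ipt_windows))
  over <- positions[, 2] + r > yb
  if (any(over)) {
    xs <- positions[over, 1, drop = TRUE]
    ys <- positions[over, 2, drop = TRUE]
    # half-width of the disc chord lying beyond the crossing boundary
    hw <- ifelse(ys >= yb, r, sqrt(pmax(0, r^2 - (yb - ys)^2)))
    lo <- geom$ipt_windows[, "lo"]
    hi <- geom$ipt_windows[, "hi"]
    for (i in seq_along(xs)) {
      hit <- xs[i] + hw[i] > lo & xs[i] - hw[i] < hi
      crossings[hit] <- TRUE
    }
  }
  max_d <- if (nrow(positions) == 0) 0 else
    max(0, max(positions[, 2]) + r - geom$post_center_y_um)
  list(crossings = crossings,
       n_ipts_crossed = sum(crossings),
       max_distance_um = max_d)
}

disc_pixels <- function(xc, yc, r, grid) {
  # pixel centers of the acquisition grid strictly inside the disc
  u <- grid$um_per_px
  jr <- seq(max(1, floor((xc - r - grid$region[1]) / u)),
            min(grid$width_px, ceiling((xc + r - grid$region[1]) / u + 1)))
  ir <- seq(max(1, floor((grid$region[4] - yc - r) / u)),
            min(grid$height_px, ceiling((grid$region[4] - yc + r) / u + 1)))
  if (length(jr) == 0 || length(ir) == 0) return(NULL)
  px <- grid$region[1] + (jr - 0.5) * u
  py <- grid$region[4] - (ir - 0.5) * u
  g <- expand.grid(x = px, y = py)
  keep <- (g$x - xc)^2 + (g$y - yc)^2 < r^2
  if (!any(keep)) return(NULL)
  g[keep, , drop = FALSE]
}

score_positions_grid <- function(positions, geom, r, grid) {
  yb <- geom$crossing_boundary_y_um
  crossings <- rep(FALSE, nrow(geom$ipt_windows))
  max_d <- 0
  for (i in seq_len(nrow(positions))) {
    # cells far below the reference lines cannot contribute to either
    # metric; skip the pixel enumeration for them
    if (positions[i, 2] + r <= geom$post_center_y_um) next
    g <- disc_pixels(positions[i, 1], positions[i, 2], r, grid)
    if (is.null(g)) next
    max_d <- max(max_d, max(g$y) - geom$post_center_y_um)
    over <- g$y > yb
    if (any(over)) {
      w <- ipt_window_of(geom, g$x[over])
      crossings[unique(w[!is.na(w)])] <- TRUE
    }
  }
  list(crossings = crossings, n_ipts_crossed = sum(crossings),
       max_distance_um = max(0, max_d))
}

#' Fold difference between two group summaries
#'
#' @param a,b positive scalars (e.g. group mean maximum distances);
#'   \code{b} is the reference.
#' @return \code{a / b}. Report tables round to one decimal.
#' @export
fold_difference <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1, is.finite(a), is.finite(b))
  if (b <= 0) stop("undefined ratio: reference value must be positive")
  a / b
}

#' Day-over-day change in invasion metrics
#'
#' Ratio of day-2 to day-1 metrics for one chip. When the day-1 value is
#' zero the fold is undefined and returned as NA with a flag, never as
#' infinity.
#'
#' @param score_d2,score_d1 \code{invasion_score} records for the same
#'   chip on days 2 and 1.
#' @return List with \code{ipt_fold}, \code{distance_fold} and
#'   \code{undefined} (character vector naming metrics with a zero day-1
#'   baseline).
#' @export
day_over_day_change <- function(score_d2, score_d1) {
  stopifnot(inherits(score_d2, "invasion_score"),
            inherits(score_d1, "invasion_score"))
  if (!identical(score_d2$chip_id, score_d1$chip_id))
    stop("pairing error: scores are from different chips (",
         score_d2$chip_id, " vs ", score_d1$chip_id, ")")
  if (!(score_d1$day == 1 && score_d2$day == 2))
    stop("pairing error: expected day-1 and day-2 scores")
  undef <- character()
  ipt_fold <- if (score_d1$n_ipts_crossed == 0) {
    undef <- c(undef, "n_ipts_crossed"); NA_real_
  } else score_d2$n_ipts_crossed / score_d1$n_ipts_crossed
  dist_fold <- if (score_d1$max_distance_um == 0) {
    undef <- c(undef, "max_distance_um"); NA_real_
  } else score_d2$max_distance_um / score_d1$max_distance_um
  list(ipt_fold = ipt_fold, distance_fold = dist_fold, undefined = undef)
}

#' Invasion scores as a data frame
#'
#' @param scores list of \code{invasion_score}.
#' @return data.frame with one row per score: chip_id, day, cell_line,
#'   dose_uM, n_ipts_crossed, max_distance_um, and crossings encoded as a
#'   0/1 string (one character per window).
#' @export
scores_to_df <- function(scores) {
  if (length(scores) == 0)
    return(data.frame(chip_id = character(), day = integer(),
                      cell_line = character(), dose_uM = numeric(),
                      n_ipts_crossed = integer(),
                      max_distance_um = numeric(), crossings = character()))
  data.frame(
    chip_id = vapply(scores, function(s) as.character(s$chip_id), character(1)),
    day = vapply(scores, function(s) s$day, integer(1)),
    cell_line = vapply(scores, function(s) as.character(s$cell_line), character(1)),
    dose_uM = vapply(scores, function(s) as.numeric(s$dose_uM), numeric(1)),
    n_ipts_crossed = vapply(scores, function(s) as.integer(s$n_ipts_crossed), integer(1)),
    max_distance_um = vapply(scores, function(s) s$max_distance_um, numeric(1)),
    crossings = vapply(scores, function(s)
      paste(as.integer(s$crossings), collapse = ""), character(1))
  )
}

#' Long-format experiment table
#'
#' Melts a per-chip score table into one record per (chip, day, metric),
#' the layout consumed by the statistics functions.
#'
#' @param scores_df data.frame from \code{\link{scores_to_df}}.
#' @return data.frame with columns cell_line, day, dose_uM, chip_id,
#'   metric_name, value.
#' @export
as_experiment_table <- function(scores_df) {
  need <- c("chip_id", "day", "cell_line", "dose_uM",
            "n_ipts_crossed", "max_distance_um")
  if (!all(need %in% names(scores_df)))
    stop("scores_df missing columns: ",
         paste(setdiff(need, names(scores_df)), collapse = ", "))
  long <- rbind(
    data.frame(scores_df[c("cell_line", "day", "dose_uM", "chip_id")],
               metric_name = "n_ipts_crossed",
               value = as.numeric(scores_df$n_ipts_crossed)),
    data.frame(scores_df[c("cell_line", "day", "dose_uM", "chip_id")],
               metric_name = "max_distance_um",
               value = scores_df$max_distance_um)
  )
  if (any(long$value < 0)) stop("metric values must be non-negative")
  rownames(long) <- NULL
  long
}
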