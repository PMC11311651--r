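#' Simulation parameters
#'
#' Parameters of the agent-based migration model: a biased random walk in
#' which each cell takes Gaussian steps with a deterministic drift toward
#' the upper (10% FBS) channel, reflecting off the posts and the channel
#' walls. The chemotactic gradient enters only as the drift direction;
#' migrastatic inhibition rescales the drift by \code{1 / (1 + dose/IC50)}.
#' The non-invasive phenotype has zero drift and is seeded in clusters,
#' emulating the cluster-forming, non-migrating low-grade line.
#'
#' Defaults are a synthetic calibration, not measured rates: they are
#' chosen once so that the default arms reproduce the assay's qualitative
#' orderings (invasive lines cross many IPTs and invade hundreds of um by
#' day 2; the non-invasive line stays inside the central channel; higher
#' inhibitor dose means less invasion).
#'
#' @param phenotype \code{"invasive"} or \code{"non_invasive"}.
#' @param drift_um_per_step mean displacement toward the upper channel per
#'   step, um. Must be 0 for the non-invasive phenotype. Default 7
#'   (invasive) or 0.
#' @param diffusion_um per-step isotropic displacement SD, um. Default 6
#'   (invasive) or 2 (non-invasive).
#' @param steps_per_day walk steps per culture day (default 24, i.e.
#'   hourly updates).
#' @param n_cells agents per chip (default 400; a compute-scaled stand-in
#'   for the assay's seeding density, sufficient because the scored
#'   metrics depend only on the invasion front).
#' @param clustering_radius_um seeding cluster SD scale for the
#'   non-invasive phenotype, um (default 150).
#' @param dose_uM inhibitor dose (default 0).
#' @param ic50_uM dose at which drift is halved (default 1, the low end
#'   of the assayed 0/1/10/100 uM range).
#' @param seed RNG seed for the chip.
#' @return Object of class \code{simulation_params}.
#' @export
simulation_params <- function(phenotype = c("invasive", "non_invasive"),
                              drift_um_per_step = NULL,
                              diffusion_um = NULL,
                              steps_per_day = 24, n_cells = 400,
                              clustering_radius_um = 150,
                              dose_uM = 0, ic50_uM = 1, seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (is.null(drift_um_per_step))
    drift_um_per_step <- if (phenotype == "invasive") 7 else 0
  if (is.null(diffusion_um))
    diffusion_um <- if (phenotype == "invasive") 6 else 2
  if (phenotype == "non_invasive" && drift_um_per_step != 0)
    stop("non-invasive phenotype must have zero drift")
  stopifnot(drift_um_per_step >= 0, diffusion_um >= 0,
            steps_per_day >= 1, n_cells >= 1,
            clustering_radius_um > 0, dose_uM >= 0, ic50_uM > 0)
  structure(list(phenotype = phenotype,
                 drift_um_per_step = drift_um_per_step,
                 diffusion_um = diffusion_um,
                 steps_per_day = as.integer(steps_per_day),
                 n_cells = as.integer(n_cells),
                 clustering_radius_um = clustering_radius_um,
                 dose_uM = dose_uM, ic50_uM = ic50_uM,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Effective drift under inhibition
#'
#' \code{drift / (1 + dose / IC50)}: a saturating one-site inhibition law;
#' at \code{dose = IC50} the drift is exactly halved.
#'
#' @param params a \code{simulation_params}.
#' @return Effective drift, um per step.
#' @export
effective_drift <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  params$drift_um_per_step / (1 + params$dose_uM / params$ic50_uM)
}

sim_bounds <- function(geom) {
  r <- geom$post_diameter_um / 2
  list(x = geom$active_window_x_um,
       y = c(-(r + geom$channel_width_um), r + geom$channel_width_um),
       post_r = r)
}

reflect_interval <- function(v, lo, hi) {
  # fold coordinates into [lo, hi]; step sizes are far below the interval
  # width so two passes always suffice
  for (k in 1:2) {
    v <- ifelse(v < lo, 2 * lo - v, v)
    v <- ifelse(v > hi, 2 * hi - v, v)
  }
  pmin(pmax(v, lo), hi)
}

reflect_posts <- function(pos, prev, geom, bounds) {
  r <- bounds$post_r
  near <- which(abs(pos[, 2]) < r)
  if (length(near) == 0) return(pos)
  centers <- geom$post_centers_x_um
  pitch <- geom$post_diameter_um + geom$post_gap_um
  k <- pmin(pmax(round((pos[near, 1] - centers[1]) / pitch) + 1, 1),
            geom$n_posts)
  dx <- pos[near, 1] - centers[k]
  dy <- pos[near, 2]
  d <- sqrt(dx^2 + dy^2)
  inside <- d < r
  if (!any(inside)) return(pos)
  i <- near[inside]
  di <- d[inside]
  ok <- di > 1e-9
  scl <- ifelse(ok, (2 * r - di) / di, 0)
  newx <- centers[k][inside] + scl * dx[inside]
  newy <- scl * dy[inside]
  # radial reflection; if it lands out of bounds or in a post again
  # (cannot happen for default geometry, guarded anyway), revert the move
  k2 <- pmin(pmax(round((newx - centers[1]) / pitch) + 1, 1), geom$n_posts)
  bad <- !ok |
    sqrt((newx - centers[k2])^2 + newy^2) < r |
    newx < bounds$x[1] | newx > bounds$x[2] |
    newy < bounds$y[1] | newy > bounds$y[2]
  pos[i[!bad], 1] <- newx[!bad]
  pos[i[!bad], 2] <- newy[!bad]
  pos[i[bad], ] <- prev[i[bad], , drop = FALSE]
  pos
}

seed_positions <- function(params, geom, bounds) {
  n <- params$n_cells
  ytop <- -bounds$post_r            # just below the post row
  if (params$phenotype == "invasive") {
    cbind(stats::runif(n, bounds$x[1], bounds$x[2]),
          stats::runif(n, bounds$y[1], ytop))
  } else {
    # clustered seeding: cohesive colonies, no attractive dynamics needed
    ncl <- max(1L, round(n / 60))
    cr <- params$clustering_radius_um
    cx <- stats::runif(ncl, bounds$x[1] + cr, bounds$x[2] - cr)
    cy <- stats::runif(ncl, bounds$y[1] + cr, ytop - cr / 2)
    pick <- sample.int(ncl, n, replace = TRUE)
    pos <- cbind(stats::rnorm(n, cx[pick], cr / 2),
                 stats::rnorm(n, cy[pick], cr / 2))
    pos[, 1] <- pmin(pmax(pos[, 1], bounds$x[1]), bounds$x[2])
    pos[, 2] <- pmin(pmax(pos[, 2], bounds$y[1]), ytop)
    pos
  }
}

#' Simulate one chip
#'
#' Runs the biased random walk for \code{n_days} days and returns one
#' state per day, day 0 (seeding) included. Cells are seeded uniformly in
#' the central channel (clustered for the non-invasive phenotype); each
#' step adds \code{(dx, dy)} with \code{dx ~ N(0, diffusion)} and
#' \code{dy ~ N(effective_drift, diffusion)}; moves into a post disc or
#' past an outer wall are reflected. Fully reproducible for a fixed
#' \code{params$seed}.
#'
#' @param params a \code{\link{simulation_params}}.
#' @param geom a \code{\link{build_geometry}} result.
#' @param n_days number of simulated days (>= 1).
#' @return List of \code{sim_state} objects (positions matrix, day,
#'   geometry) of length \code{n_days + 1}, with the effective drift in
#'   attribute \code{"effective_drift"}.
#' @export
simulate_chip <- function(params, geom, n_days) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(geom, "chip_geometry"))
  if (length(n_days) != 1 || n_days < 1 || n_days != round(n_days))
    stop("n_days must be a positive integer")
  bounds <- sim_bounds(geom)
  set.seed(params$seed)
  pos <- seed_positions(params, geom, bounds)
  drift <- effective_drift(params)
  mk_state <- function(p, day) structure(
    list(positions = unname(p), day = day, geometry = geom),
    class = "sim_state")
  states <- vector("list", n_days + 1)
  states[[1]] <- mk_state(pos, 0)
  n <- params$n_cells
  for (day in seq_len(n_days)) {
    for (s in seq_len(params$steps_per_day)) {
      prev <- pos
      step <- cbind(stats::rnorm(n, 0, params$diffusion_um),
                    stats::rnorm(n, drift, params$diffusion_um))
      pos <- pos + step
      pos[, 1] <- reflect_interval(pos[, 1], bounds$x[1], bounds$x[2])
      pos[, 2] <- reflect_interval(pos[, 2], bounds$y[1], bounds$y[2])
      pos <- reflect_posts(pos, prev, geom, bounds)
    }
    states[[day + 1]] <- mk_state(pos, day)
  }
  attr(states, "effective_drift") <- drift
  attr(states, "params") <- params
  states
}

#' @export
print.sim_state <- function(x, ...) {
  cat("sim_state: day", x$day, "-", nrow(x$positions), "cells, max y",
      round(max(x$positions[, 2]), 1), "um\n")
  invisible(x)
}

#' Estimate effective drift from segmented images
#'
#' Estimates the per-step drift as the change in the mean furthest-pixel
#' y between two imaging time points, divided by the number of walk steps
#' between them. The footprint-radius offset is identical at both time
#' points and cancels.
#'
#' @param dets_t0,dets_t1 detection lists at the earlier/later time point.
#' @param n_steps number of walk steps between the two time points.
#' @return Estimated drift, um per step.
#' @export
estimate_drift <- function(dets_t0, dets_t1, n_steps) {
  stopifnot(length(dets_t0) > 0, length(dets_t1) > 0, n_steps >= 1)
  fy <- function(dets) mean(vapply(dets, function(d)
    max(d$footprint_um[, 2]), numeric(1)))
  (fy(dets_t1) - fy(dets_t0)) / n_steps
}
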