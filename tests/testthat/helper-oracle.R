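# Test helpers: independent brute-force scoring oracle and fixture builders.

# Build a minimal cell_detection from a footprint in um coordinates
# (1 um/px identity calibration).
make_detection <- function(footprint_um, modality = "fluorescence") {
  fp <- matrix(as.numeric(footprint_um), ncol = 2)
  colnames(fp) <- c("x_um", "y_um")
  structure(list(centroid_um = colMeans(fp),
                 footprint_px = fp,
                 footprint_um = fp,
                 area_um2 = nrow(fp),
                 modality = modality),
            class = "cell_detection")
}

# Disc-shaped footprint on the integer grid around a center.
disc_footprint <- function(xc, yc, r) {
  g <- expand.grid(x = seq(floor(xc - r), ceiling(xc + r)),
                   y = seq(floor(yc - r), ceiling(yc + r)))
  g <- g[(g$x - xc)^2 + (g$y - yc)^2 <= r^2, ]
  as.matrix(g)
}

# Random detection set spanning the active window and both sides of the
# post row.
random_detections <- function(n_cells, geom) {
  lapply(seq_len(n_cells), function(i) {
    xc <- runif(1, geom$active_window_x_um[1] - 100,
                geom$active_window_x_um[2] + 100)
    yc <- runif(1, -250, 250)
    make_detection(disc_footprint(xc, yc, runif(1, 1, 12)))
  })
}

# Exhaustive per-pixel brute force: loops over every footprint pixel and
# every window; deliberately naive and independent of the implementation.
oracle_score <- function(dets, geom) {
  nw <- nrow(geom$ipt_windows)
  cross <- rep(FALSE, nw)
  maxd <- 0
  for (d in dets) {
    for (i in seq_len(nrow(d$footprint_um))) {
      x <- d$footprint_um[i, 1]
      y <- d$footprint_um[i, 2]
      if (y - geom$post_center_y_um > maxd)
        maxd <- y - geom$post_center_y_um
      if (y > geom$crossing_boundary_y_um) {
        for (k in seq_len(nw)) {
          if (x >= geom$ipt_windows[k, 1] && x < geom$ipt_windows[k, 2])
            cross[k] <- TRUE
        }
      }
    }
  }
  list(crossings = cross, max_distance_um = max(0, maxd))
}

# Small rendered fixture: one simulated state with few cells.
tiny_state <- function(positions, geom = build_geometry()) {
  structure(list(positions = matrix(positions, ncol = 2),
                 day = 1L, geometry = geom),
            class = "sim_state")
}
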