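geom <- build_geometry()

test_that("simulation params validate and apply phenotype defaults", {
  p <- simulation_params("invasive")
  expect_equal(p$drift_um_per_step, 7)
  q <- simulation_params("non_invasive")
  expect_equal(q$drift_um_per_step, 0)
  expect_error(simulation_params("non_invasive", drift_um_per_step = 2),
               "zero drift")
  expect_error(simulation_params("invasive", diffusion_um = -1), "diffusion")
  expect_error(simulate_chip(p, geom, 0), "positive integer")
})

test_that("inhibition law halves drift at IC50 and is monotone", {
  p <- simulation_params("invasive", dose_uM = 1, ic50_uM = 1)
  expect_equal(effective_drift(p), p$drift_um_per_step / 2)
  drifts <- vapply(c(0, 1, 10, 100), function(d)
    effective_drift(simulation_params("invasive", dose_uM = d)), numeric(1))
  expect_true(all(diff(drifts) < 0))
  expect_equal(drifts[1], 7)
})

test_that("simulation is deterministic and frozen dynamics stay frozen", {
  p <- simulation_params("invasive", seed = 123)
  s1 <- simulate_chip(p, geom, 2)
  s2 <- simulate_chip(p, geom, 2)
  expect_identical(lapply(s1, `[[`, "positions"),
                   lapply(s2, `[[`, "positions"))
  expect_length(s1, 3)
  expect_equal(vapply(s1, `[[`, numeric(1), "day"), 0:2)
  pf <- simulation_params("invasive", drift_um_per_step = 0,
                          diffusion_um = 0, seed = 5)
  sf <- simulate_chip(pf, geom, 2)
  expect_identical(sf[[1]]$positions, sf[[3]]$positions)
})

test_that("trajectories respect posts and walls at every step", {
  # one snapshot per step so the invariant is checked exhaustively
  for (phen in c("invasive", "non_invasive")) {
    p <- simulation_params(phen, steps_per_day = 1, n_cells = 200,
                           seed = 77)
    states <- simulate_chip(p, geom, n_days = 48)
    r <- geom$post_diameter_um / 2
    ymax <- r + geom$channel_width_um
    for (st in states) {
      pos <- st$positions
      expect_true(all(pos[, 1] >= geom$active_window_x_um[1] &
                      pos[, 1] <= geom$active_window_x_um[2]))
      expect_true(all(abs(pos[, 2]) <= ymax))
      near <- which(abs(pos[, 2]) < r)
      for (i in near) {
        dmin <- min(sqrt((geom$post_centers_x_um - pos[i, 1])^2 +
                         pos[i, 2]^2))
        expect_gte(dmin, r)
      }
    }
  }
})

test_that("mean y-displacement matches S * effective_drift within 3 SE", {
  # wide channel so boundary reflections are negligible
  wide <- build_geometry(channel_width_um = 20000)
  p <- simulation_params("invasive", drift_um_per_step = 2,
                         diffusion_um = 3, steps_per_day = 5,
                         n_cells = 1000, seed = 19)
  st <- simulate_chip(p, wide, 1)
  disp <- mean(st[[2]]$positions[, 2] - st[[1]]$positions[, 2])
  se <- 3 * sqrt(5) / sqrt(1000)
  expect_lt(abs(disp - 5 * 2), 3 * se)
  # with dose at IC50 the realized mean displacement halves
  pd <- simulation_params("invasive", drift_um_per_step = 2,
                          diffusion_um = 3, steps_per_day = 5,
                          n_cells = 1000, dose_uM = 1, ic50_uM = 1,
                          seed = 19)
  sd_ <- simulate_chip(pd, wide, 1)
  dispd <- mean(sd_[[2]]$positions[, 2] - sd_[[1]]$positions[, 2])
  expect_lt(abs(dispd - 5), 3 * se)
})

test_that("render draws blobs at cell positions with stated SNR structure", {
  st <- tiny_state(cbind(c(1000, 3000), c(-200, 50)), geom)
  grid <- acquisition_grid(geom)
  set.seed(8)
  rs <- render_state(st, grid, psf_sigma_um = 4, snr = 50)
  px <- rs$image$pixels
  ctr <- to_pixel(grid$calibration, st$positions)
  for (i in 1:2)
    expect_gt(px[round(ctr[i, 2]), round(ctr[i, 1])], 900)
  expect_lt(abs(mean(px[1:200, 1:200]) - 100), 5)    # background corner
  expect_equal(nrow(rs$truth), 2)
  expect_true(all(rs$truth$labeled))
  # determinism under a fixed seed
  set.seed(8)
  rs2 <- render_state(st, grid, psf_sigma_um = 4, snr = 50)
  expect_identical(px, rs2$image$pixels)
})

test_that("labeled_fraction renders a subset; brightfield shows all cells", {
  set.seed(14)
  pos <- cbind(runif(40, 200, 5600), runif(40, -900, -100))
  st <- tiny_state(pos, geom)
  grid <- acquisition_grid(geom)
  set.seed(2)
  fl <- render_state(st, grid, labeled_fraction = 0.5)
  expect_equal(sum(fl$truth$labeled), 20)
  set.seed(3)
  bf <- render_state(st, grid, modality = "brightfield")
  dets_fl <- segment_cells(fl$image, 20, fl$threshold)
  dets_bf <- segment_cells(bf$image, 20, bf$threshold)
  expect_equal(length(dets_bf), 40)
  expect_equal(length(dets_fl), 20)
  expect_equal(positivity_rate(dets_bf, dets_fl), 0.5)
})

test_that("drift is recoverable from rendered + segmented images", {
  p <- simulation_params("invasive", n_cells = 500, seed = 31)
  states <- simulate_chip(p, geom, 1)
  grid <- acquisition_grid(geom)
  set.seed(6)
  r0 <- render_state(states[[1]], grid)
  r1 <- render_state(states[[2]], grid)
  d0 <- segment_cells(r0$image, 30, r0$threshold)
  d1 <- segment_cells(r1$image, 30, r1$threshold)
  est <- estimate_drift(d0, d1, n_steps = p$steps_per_day)
  expect_lt(abs(est - 7) / 7, 0.15)
})
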