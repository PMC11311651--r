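geom <- build_geometry()

test_that("crossing and distance basics", {
  expect_equal(score_crossings(list(), geom), rep(FALSE, 17))
  expect_equal(max_invasion_distance(list(), geom), 0)
  # one pixel just beyond the boundary inside window 5
  w5 <- ipt_window(geom, 5)
  d <- make_detection(cbind(mean(w5), 76))
  cr <- score_crossings(list(d), geom)
  expect_true(cr[5])
  expect_equal(sum(cr), 1)
  # a cell spanning a window boundary marks both windows
  b <- ipt_window(geom, 9)[["lo"]]
  d2 <- make_detection(cbind(c(b - 3, b + 3), c(80, 80)))
  expect_equal(which(score_crossings(list(d2), geom)), c(8L, 9L))
  # below the outer edge: no crossing, but distance counts from center line
  d3 <- make_detection(cbind(500, 40))
  expect_false(any(score_crossings(list(d3), geom)))
  expect_equal(max_invasion_distance(list(d3), geom), 40)
  # everything below the center line clamps to 0
  d4 <- make_detection(disc_footprint(300, -50, 5))
  expect_equal(max_invasion_distance(list(d4), geom), 0)
  expect_equal(max_invasion_distance(list(make_detection(cbind(500, 170))),
                                     geom), 170)
})

test_that("count_ipts validates and counts", {
  expect_equal(count_ipts(rep(FALSE, 17)), 0)
  expect_equal(count_ipts(rep(TRUE, 17)), 17)
  expect_error(count_ipts(rep(TRUE, 16)), "length")
  expect_error(count_ipts(c(rep(TRUE, 16), NA)), "NA")
  set.seed(4)
  for (i in 1:20) {
    v <- runif(17) > 0.5
    expect_equal(count_ipts(v), sum(sapply(v, isTRUE)))
  }
})

test_that("scoring equals the exhaustive brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    dets <- random_detections(50, geom)
    orc <- oracle_score(dets, geom)
    expect_identical(score_crossings(dets, geom), orc$crossings)
    expect_equal(max_invasion_distance(dets, geom), orc$max_distance_um)
  }
})

test_that("any crossing implies max distance >= outer-edge offset", {
  set.seed(55)
  for (rep in 1:40) {
    dets <- random_detections(20, geom)
    if (any(score_crossings(dets, geom)))
      expect_gte(max_invasion_distance(dets, geom), 75)
  }
})

test_that("metrics are equivariant under joint translation", {
  set.seed(77)
  dets <- random_detections(30, geom)
  shift <- c(123.4, -56.7)
  geom2 <- geom
  geom2$post_centers_x_um <- geom$post_centers_x_um + shift[1]
  geom2$active_window_x_um <- geom$active_window_x_um + shift[1]
  geom2$ipt_windows <- geom$ipt_windows + shift[1]
  geom2$post_center_y_um <- geom$post_center_y_um + shift[2]
  geom2$crossing_boundary_y_um <- geom$crossing_boundary_y_um + shift[2]
  dets2 <- lapply(dets, function(d) {
    fp <- sweep(d$footprint_um, 2, shift, "+")
    make_detection(fp)
  })
  expect_identical(score_crossings(dets2, geom2),
                   score_crossings(dets, geom))
  expect_equal(max_invasion_distance(dets2, geom2),
               max_invasion_distance(dets, geom))
})

test_that("score_positions (continuous and grid) agrees with pixel oracle", {
  set.seed(202)
  grid <- acquisition_grid(geom)
  for (rep in 1:5) {
    pos <- cbind(runif(40, 0, 5800), runif(40, -200, 200))
    r <- 4.5
    gt <- score_positions(pos, geom, r, grid = grid)
    # oracle: build explicit pixel-footprint detections on the same grid
    dets <- lapply(seq_len(nrow(pos)), function(i) {
      g <- expand.grid(x = seq(0.5, 5799.5),
                       y = seq(floor(pos[i, 2]) - 6 + 0.5,
                               ceiling(pos[i, 2]) + 6 - 0.5))
      g <- g[(g$x - pos[i, 1])^2 + (g$y - pos[i, 2])^2 < r^2, ]
      if (nrow(g) == 0) NULL else make_detection(as.matrix(g))
    })
    dets <- Filter(Negate(is.null), dets)
    orc <- oracle_score(dets, geom)
    expect_identical(gt$crossings, orc$crossings)
    expect_equal(gt$max_distance_um, orc$max_distance_um)
    # continuous-disc scoring dominates the discretized version
    cont <- score_positions(pos, geom, r)
    expect_true(all(gt$crossings <= cont$crossings))
    expect_lte(gt$max_distance_um, cont$max_distance_um)
  }
})

test_that("fold differences and day-over-day changes", {
  expect_equal(round(fold_difference(247.5, 46.7), 1), 5.3)
  expect_equal(round(fold_difference(276.6, 46.7), 1), 5.9)
  expect_equal(fold_difference(3.7, 3.7), 1)
  expect_error(fold_difference(1, 0), "positive")

  mk_score <- function(day, n, d, id = "c1") {
    cr <- rep(FALSE, 17); if (n > 0) cr[seq_len(n)] <- TRUE
    structure(list(chip_id = id, day = day, crossings = cr,
                   n_ipts_crossed = n, max_distance_um = d,
                   n_downward = 0L, dose_uM = 0, cell_line = "x"),
              class = "invasion_score")
  }
  ch <- day_over_day_change(mk_score(2L, 9, 250), mk_score(1L, 3, 100))
  expect_equal(ch$ipt_fold, 3)
  expect_equal(ch$distance_fold, 2.5)
  expect_length(ch$undefined, 0)
  ch0 <- day_over_day_change(mk_score(2L, 4, 80), mk_score(1L, 0, 0))
  expect_true(is.na(ch0$ipt_fold))
  expect_setequal(ch0$undefined, c("n_ipts_crossed", "max_distance_um"))
  expect_error(day_over_day_change(mk_score(2L, 1, 1, "a"),
                                   mk_score(1L, 1, 1, "b")), "pairing")
})

test_that("score_chip assembles records and flags downward invasion", {
  dets <- list(make_detection(cbind(400, 100)),
               make_detection(cbind(900, -90)))
  expect_message(s <- score_chip(dets, geom, "chipA", 2), "not scored")
  expect_equal(s$n_ipts_crossed, 1)
  expect_equal(s$max_distance_um, 100)
  expect_equal(s$n_downward, 1L)
  df <- scores_to_df(list(s))
  expect_equal(nchar(df$crossings), 17)
  tab <- as_experiment_table(df)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$metric_name, c("n_ipts_crossed", "max_distance_um"))
})
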