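# Fixed toy table used across the ANOVA/Tukey oracle checks.
toy <- list(a = c(1, 2, 3, 4), b = c(3, 5, 4, 8), c = c(7, 9, 8, 12))

test_that("one-way ANOVA matches the hand-computed decomposition", {
  # SS_between = 4[(2.5-5.5)^2 + (5-5.5)^2 + (9-5.5)^2] = 86
  # SS_within  = 5 + 14 + 14 = 33; F = (86/2) / (33/9) = 387/33
  fit <- one_way_anova(toy)
  expect_equal(fit$F, 387 / 33, tolerance = 1e-12)
  expect_equal(fit$df, c(2, 9))
  expect_equal(fit$group_means, c(a = 2.5, b = 5, c = 9))
  expect_equal(fit$p, pf(387 / 33, 2, 9, lower.tail = FALSE))
  # independent route through base R's linear-model ANOVA
  df <- data.frame(y = unlist(toy),
                   g = rep(names(toy), lengths(toy)))
  ref <- anova(lm(y ~ g, data = df))
  expect_equal(fit$F, ref$`F value`[1])
  expect_equal(fit$p, ref$`Pr(>F)`[1])
})

test_that("ANOVA equals squared pooled t for two groups", {
  set.seed(9)
  g <- list(rnorm(6), rnorm(8, 1))
  fit <- one_way_anova(g)
  tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2)
  expect_equal(fit$p, tt$p.value)
})

test_that("ANOVA validation and degenerate cases", {
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "at least 2 observations")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_warning(fit <- one_way_anova(list(c(1, 1), c(2, 2))),
                 "zero within-group")
  expect_equal(fit$p, 0)
})

test_that("ANOVA F is invariant to shift and positive scaling", {
  set.seed(12)
  g <- lapply(1:3, function(i) rnorm(5, i))
  f0 <- one_way_anova(g)$F
  expect_equal(one_way_anova(lapply(g, function(x) x + 100))$F, f0)
  expect_equal(one_way_anova(lapply(g, function(x) x * 3.7))$F, f0)
})

test_that("Tukey HSD matches direct formula and base TukeyHSD", {
  tk <- tukey_hsd(toy)
  # direct studentized-range statistic for pair (a, b)
  msw <- 33 / 9
  q_ab <- abs(2.5 - 5) / sqrt(msw / 2 * (1 / 4 + 1 / 4))
  expect_equal(tk$q[tk$group1 == "a" & tk$group2 == "b"], q_ab)
  expect_equal(tk$p_adj,
               ptukey(tk$q, 3, 9, lower.tail = FALSE))
  df <- data.frame(y = unlist(toy), g = factor(rep(names(toy), each = 4)))
  ref <- TukeyHSD(aov(y ~ g, data = df))$g
  ref <- ref[order(rownames(ref)), ]
  key <- paste0(tk$group2, "-", tk$group1)
  expect_equal(tk$p_adj[order(key)], unname(ref[, "p adj"]),
               tolerance = 1e-10)
  expect_equal(-tk$mean_diff[order(key)], unname(ref[, "diff"]))
})

test_that("Tukey null case, symmetry, and conservativeness", {
  eq <- list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1))
  tk <- tukey_hsd(eq)
  expect_equal(tk$q, rep(0, 3))
  expect_equal(tk$p_adj, rep(1, 3))
  # order of groups does not change q or p
  tk2 <- tukey_hsd(rev(eq))
  expect_setequal(round(tk2$q, 12), round(tk$q, 12))
  # p_adj never below the raw pairwise pooled-t p (k > 2)
  set.seed(31)
  for (i in 1:10) {
    g <- lapply(1:4, function(j) rnorm(5, j / 3))
    tk <- tukey_hsd(g)
    fit <- one_way_anova(g)
    for (r in seq_len(nrow(tk))) {
      i1 <- as.integer(sub("group", "", tk$group1[r]))
      i2 <- as.integer(sub("group", "", tk$group2[r]))
      se <- sqrt(fit$ms_within * (1 / 5 + 1 / 5))
      traw <- abs(fit$group_means[i1] - fit$group_means[i2]) / se
      praw <- 2 * pt(traw, fit$df[2], lower.tail = FALSE)
      expect_gte(tk$p_adj[r] + 1e-12, praw)
    }
  }
})

test_that("significance stars follow the dose-figure convention", {
  expect_equal(significance_stars(c(0.5, 0.009, 0.0009, 0.00009, NA)),
               c("ns", "*", "**", "***", NA))
  expect_error(significance_stars(2), "p")
})

test_that("dose-response summary and trend flag", {
  tab <- data.frame(
    cell_line = "x", day = 2,
    dose_uM = rep(c(0, 1, 10, 100), each = 3),
    chip_id = paste0("c", 1:12),
    metric_name = "n_ipts_crossed",
    value = c(16, 17, 16, 12, 11, 13, 2, 1, 0, 0, 0, 1))
  ds <- dose_response_summary(tab, "n_ipts_crossed")
  expect_true(ds$monotone_decreasing)
  expect_equal(ds$summary$mean, c(49 / 3, 12, 1, 1 / 3))
  # constant means count as non-increasing
  tab$value <- 5
  expect_true(dose_response_summary(tab, "n_ipts_crossed")$monotone_decreasing)
  # an increasing pair flips the flag
  tab$value <- c(1, 1, 1, 5, 5, 5, 0, 0, 0, 0, 0, 0)
  expect_false(dose_response_summary(tab, "n_ipts_crossed")$monotone_decreasing)
  expect_error(dose_response_summary(tab[tab$dose_uM == 0, ],
                                     "n_ipts_crossed"), "dose levels")
})

test_that("compare_groups wires metrics, grouping and stars together", {
  set.seed(41)
  tab <- do.call(rbind, lapply(c("inv1", "inv2", "noninv"), function(cl) {
    mu <- if (cl == "noninv") 0.5 else 14
    data.frame(cell_line = cl, day = 2, dose_uM = 0,
               chip_id = paste0(cl, 1:4),
               metric_name = "n_ipts_crossed",
               value = pmax(0, rnorm(4, mu, 1.5)))
  }))
  cmp <- compare_groups(tab, "n_ipts_crossed", day = 2)
  expect_s3_class(cmp, "comparison_result")
  expect_equal(nrow(cmp$tukey), 3)
  expect_lt(cmp$anova$p, 0.05)
  sig <- cmp$tukey[cmp$tukey$group2 == "noninv" |
                   cmp$tukey$group1 == "noninv", ]
  expect_true(all(sig$significant))
})
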