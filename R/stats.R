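#' One-way ANOVA
#'
#' Fixed-effects one-way analysis of variance computed from the classical
#' sums-of-squares decomposition: F = MS_between / MS_within on
#' (k - 1, N - k) degrees of freedom, p from the upper tail of the F
#' distribution.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return Object of class \code{anova_result}: \code{F}, \code{p},
#'   \code{df}, \code{ms_within}, \code{group_means}, \code{group_sds},
#'   \code{group_ns}.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  ns <- lengths(groups)
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  if (ms_within == 0) {
    if (ss_between == 0)
      stop("degenerate data: zero variance within and between groups")
    warning("zero within-group variance with unequal means; p = 0")
    f <- Inf; p <- 0
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  }
  structure(list(F = f, p = p, df = c(k - 1, N - k),
                 ms_within = ms_within,
                 group_means = means,
                 group_sds = vapply(groups, stats::sd, numeric(1)),
                 group_ns = ns),
            class = "anova_result")
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 observations")
  if (!all(vapply(groups, function(g) is.numeric(g) && all(is.finite(g)),
                  logical(1))))
    stop("groups must be finite numeric vectors")
  invisible(TRUE)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise comparisons after a one-way ANOVA. For groups i, j the
#' studentized-range statistic is
#' \code{q = |m_i - m_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))}
#' (the Tukey-Kramer form, exact for equal n), with adjusted p from the
#' studentized-range distribution on (k, N - k).
#'
#' @param groups list of numeric samples; names are used as group labels.
#' @param alpha significance level for the \code{significant} flag
#'   (default 0.05).
#' @return data.frame with one row per unordered pair: group1, group2,
#'   mean_diff (m1 - m2), q, p_adj, significant.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  check_groups(groups)
  fit <- one_way_anova(groups)
  k <- length(groups)
  nm <- names(groups) %||% paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- vapply(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1, col]; j <- pairs[2, col]
    diff <- unname(fit$group_means[i] - fit$group_means[j])
    se <- sqrt(fit$ms_within / 2 *
               (1 / fit$group_ns[[i]] + 1 / fit$group_ns[[j]]))
    q <- if (se == 0) { if (diff == 0) 0 else Inf } else abs(diff) / se
    p_adj <- if (is.infinite(q)) 0 else
      stats::ptukey(q, k, fit$df[2], lower.tail = FALSE)
    c(diff, q, p_adj)
  }, numeric(3))
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             mean_diff = res[1, ], q = res[2, ],
             p_adj = res[3, ],
             significant = res[3, ] < alpha)
}

#' Significance stars
#'
#' The star convention used in the assay's dose-response figures:
#' \code{*} p < 0.01, \code{**} p < 0.001, \code{***} p < 0.0001,
#' otherwise \code{ns}.
#'
#' @param p numeric vector of p values.
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("ns", length(p))
  out[p < 0.01] <- "*"
  out[p < 0.001] <- "**"
  out[p < 0.0001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Compare groups on one invasion metric
#'
#' Runs one-way ANOVA plus Tukey HSD on one metric of a long-format
#' experiment table, grouping by an arbitrary design column.
#'
#' @param table long-format table from \code{\link{as_experiment_table}}.
#' @param metric_name \code{"n_ipts_crossed"} or \code{"max_distance_um"}.
#' @param group_by grouping column (default \code{"cell_line"}).
#' @param day restrict to one day (optional).
#' @param alpha significance level (default 0.05).
#' @return List of class \code{comparison_result}: \code{anova},
#'   \code{tukey}, \code{group_means}, \code{group_sds}, \code{metric},
#'   \code{day}.
#' @export
compare_groups <- function(table, metric_name, group_by = "cell_line",
                           day = NULL, alpha = 0.05) {
  stopifnot(metric_name %in% table$metric_name, group_by %in% names(table))
  sub <- table[table$metric_name == metric_name, ]
  if (!is.null(day)) sub <- sub[sub$day == day, ]
  groups <- split(sub$value, sub[[group_by]])
  fit <- one_way_anova(groups)
  tk <- tukey_hsd(groups, alpha = alpha)
  tk$stars <- significance_stars(tk$p_adj)
  structure(list(anova = fit, tukey = tk,
                 group_means = fit$group_means,
                 group_sds = fit$group_sds,
                 metric = metric_name, day = day),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison of", x$metric,
      if (!is.null(x$day)) paste("on day", x$day) else "", "\n")
  print(x$anova)
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Dose-response summary
#'
#' Mean and SD of one metric per dose level, plus a monotone-trend flag
#' that is TRUE when the per-dose means are non-increasing with dose
#' (flat included) — the direction expected of a migrastatic inhibitor.
#'
#' @param table long-format experiment table.
#' @param metric_name metric to summarize.
#' @param day restrict to one day (optional).
#' @return List with \code{summary} (data.frame dose_uM, n, mean, sd) and
#'   \code{monotone_decreasing} (logical).
#' @export
dose_response_summary <- function(table, metric_name, day = NULL) {
  stopifnot(metric_name %in% table$metric_name)
  sub <- table[table$metric_name == metric_name, ]
  if (!is.null(day)) sub <- sub[sub$day == day, ]
  doses <- sort(unique(sub$dose_uM))
  if (length(doses) < 2)
    stop("dose-response summary needs at least 2 dose levels")
  agg <- do.call(rbind, lapply(doses, function(d) {
    v <- sub$value[sub$dose_uM == d]
    data.frame(dose_uM = d, n = length(v), mean = mean(v),
               sd = stats::sd(v))
  }))
  list(summary = agg,
       monotone_decreasing = all(diff(agg$mean) <= 0))
}
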