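# Rank-based comparison of event orderings. Positions are ordinal, so
# nonparametric tests are used: Wilcoxon signed-rank within a group
# (paired position samples from the same thinned chain or bootstrap
# replicates) and Mann-Whitney U between groups.

#' Does biomarker i become abnormal before biomarker j?
#'
#' One-tailed Wilcoxon signed-rank test on paired position samples
#' (small position = early event): the alternative is that `pos_i` is
#' shifted below `pos_j`. Zero differences are discarded (the standard
#' zero-discard convention); the exact distribution is used for small
#' samples without ties, the normal approximation otherwise.
#'
#' @param pos_i,pos_j Equal-length integer vectors of the two biomarkers'
#'   positions across thinned MCMC samples or bootstrap replicates.
#' @return Tibble with `statistic`, `p`, `n_effective`, `degenerate`.
#' @export
within_group_order_test <- function(pos_i, pos_j) {
  if (length(pos_i) != length(pos_j)) abort("paired vectors must have equal length")
  if (length(pos_i) < 5) abort("need at least 5 paired samples")
  d <- pos_i - pos_j
  if (all(d == 0)) {
    return(tibble(statistic = NA_real_, p = 1, n_effective = 0L,
                  degenerate = TRUE))
  }
  tst <- suppressWarnings(wilcox.test(pos_i, pos_j, paired = TRUE,
                                      alternative = "less"))
  tibble(statistic = unname(tst$statistic), p = tst$p.value,
         n_effective = sum(d != 0), degenerate = FALSE)
}

#' Is a biomarker positioned differently in two groups?
#'
#' Two-tailed Mann-Whitney U test (with tie correction) comparing one
#' biomarker's position samples between two groups, plus the
#' rank-biserial effect size `r = 2U/(n1*n2) - 1`.
#'
#' @param pos_group1,pos_group2 Position samples for the biomarker in
#'   each group.
#' @return Tibble with `statistic` (U), `p`, `effect_size`, `degenerate`.
#' @export
between_group_position_test <- function(pos_group1, pos_group2) {
  if (length(pos_group1) < 5 || length(pos_group2) < 5) {
    abort("need at least 5 samples per group")
  }
  if (length(unique(c(pos_group1, pos_group2))) == 1L) {
    return(tibble(statistic = NA_real_, p = 1, effect_size = 0,
                  degenerate = TRUE))
  }
  tst <- suppressWarnings(wilcox.test(pos_group1, pos_group2,
                                      alternative = "two.sided", exact = FALSE,
                                      correct = TRUE))
  u <- unname(tst$statistic)
  tibble(statistic = u, p = tst$p.value,
         effect_size = 2 * u / (length(pos_group1) * length(pos_group2)) - 1,
         degenerate = FALSE)
}

#' Bonferroni control over a family of tests
#'
#' Rejects where `p < alpha / m`; the corrected threshold is reported
#' alongside the decisions.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of tests in the family (defaults to
#'   `length(p_values)`; must be at least that).
#' @param alpha Family-wise error rate.
#' @return Tibble with `p`, `threshold`, `reject`.
#' @export
bonferroni_control <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < length(p_values)) abort("m must be >= the number of p-values")
  thr <- alpha / m
  tibble(p = p_values, threshold = thr, reject = !is.na(p_values) & p_values < thr)
}

#' All pairwise within-group ordering tests
#'
#' Runs [within_group_order_test()] for every ordered biomarker pair in a
#' group's position samples and applies Bonferroni control across the
#' pairs tested.
#'
#' @param positions Tibble from [position_samples()] (`biomarker`,
#'   `sample`, `position`).
#' @param alpha Family-wise error rate.
#' @return Tibble: one row per ordered pair (i, j), with statistic, p,
#'   Bonferroni threshold and decision.
#' @export
within_group_order_table <- function(positions, alpha = 0.05) {
  wide <- positions |>
    select("sample", "biomarker", "position") |>
    pivot_wider(names_from = "biomarker", values_from = "position")
  bms <- setdiff(names(wide), "sample")
  pairs <- expand.grid(i = bms, j = bms, stringsAsFactors = FALSE) |>
    filter(.data$i != .data$j)
  res <- purrr::map(seq_len(nrow(pairs)), function(k) {
    t <- within_group_order_test(wide[[pairs$i[k]]], wide[[pairs$j[k]]])
    mutate(t, biomarker_i = pairs$i[k], biomarker_j = pairs$j[k])
  }) |> list_rbind()
  ctl <- bonferroni_control(res$p, alpha = alpha)
  res |>
    mutate(threshold = ctl$threshold, reject = ctl$reject, m = nrow(res)) |>
    select("biomarker_i", "biomarker_j", "statistic", "p", "n_effective",
           "degenerate", "m", "threshold", "reject")
}

#' Between-group position tests for every biomarker
#'
#' Runs [between_group_position_test()] per biomarker on two groups'
#' position samples and applies Bonferroni control across biomarkers.
#'
#' @param positions_g1,positions_g2 Tibbles from [position_samples()].
#' @param alpha Family-wise error rate.
#' @return Tibble: one row per biomarker with U statistic, p, effect
#'   size, Bonferroni threshold and decision.
#' @export
between_group_order_table <- function(positions_g1, positions_g2, alpha = 0.05) {
  bms <- intersect(unique(positions_g1$biomarker), unique(positions_g2$biomarker))
  res <- purrr::map(bms, function(b) {
    p1 <- positions_g1$position[positions_g1$biomarker == b]
    p2 <- positions_g2$position[positions_g2$biomarker == b]
    mutate(between_group_position_test(p1, p2), biomarker = b,
           median_g1 = median(p1), median_g2 = median(p2))
  }) |> list_rbind()
  ctl <- bonferroni_control(res$p, alpha = alpha)
  res |>
    mutate(threshold = ctl$threshold, reject = ctl$reject, m = nrow(res)) |>
    select("biomarker", "median_g1", "median_g2", "statistic", "p",
           "effect_size", "degenerate", "m", "threshold", "reject")
}
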