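# Devaluation tests, nonparametric group comparisons and two-bottle
# evaporation normalisation.

# Exact distribution of the signed-rank statistic W (sum of ranks of
# positive differences) over all 2^n equiprobable sign patterns, with
# tie-averaged ranks. Ranks are doubled so averaged ranks stay integral;
# returns P(W2 = 0..sum(r2)) where W2 = 2W.
signrank_exact_dist <- function(r2) {
  M <- sum(r2)
  cf <- numeric(M + 1)
  cf[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), cf[seq_len(M + 1 - r)])
    cf <- cf + shifted
  }
  cf / 2^length(r2)
}

signed_rank_p <- function(d, exact_max_n = 25) {
  d <- d[d != 0] # zero differences dropped (classical convention)
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L, tied = TRUE,
      method = "all differences zero"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max_n) {
    dist <- signrank_exact_dist(as.integer(round(2 * r)))
    w2 <- round(2 * v)
    ple <- sum(dist[seq_len(w2 + 1)])
    pge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(ple, pge))
    method <- "exact signed-rank (full sign-pattern enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "signed-rank normal approximation (tie-corrected, continuity-corrected)"
  }
  list(statistic = v, p_value = p, n_used = n, tied = FALSE, method = method)
}

#' Paired reward-devaluation test
#'
#' Compares paired response counts from valued and devalued extinction
#' sessions with a two-sided Wilcoxon signed-rank test. The p-value is exact
#' (full enumeration of all sign patterns, ties handled by averaged ranks)
#' for up to 25 informative pairs and uses the tie-corrected normal
#' approximation above that. Zero differences are dropped; if all pairs are
#' tied the test is flagged and p = 1 by convention. Also reports the
#' per-subject devaluation index `devalued / (valued + devalued)`.
#'
#' @param pairs A data frame with numeric columns `valued` and `devalued`
#'   (one row per subject), e.g. from [simulate_devaluation_cohort()].
#' @return A `devaluation_result`: list with `pairs` (input plus `diff` and
#'   `index`), `statistic` (signed-rank V), `p_value`, `n_used`,
#'   `mean_index`, `tied`, `method`.
#' @examples
#' devaluation_test(data.frame(valued = c(30, 25, 41, 37, 28, 33),
#'                             devalued = c(12, 9, 20, 15, 11, 14)))
#' @export
devaluation_test <- function(pairs) {
  if (!all(c("valued", "devalued") %in% names(pairs))) {
    stop("`pairs` needs `valued` and `devalued` columns", call. = FALSE)
  }
  if (nrow(pairs) < 1) stop("need at least one pair", call. = FALSE)
  if (any(pairs$valued < 0) || any(pairs$devalued < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  d <- pairs$devalued - pairs$valued
  res <- signed_rank_p(d)
  tot <- pairs$valued + pairs$devalued
  idx <- ifelse(tot == 0, NaN, pairs$devalued / tot)
  structure(
    list(
      pairs = tibble::as_tibble(pairs) |>
        dplyr::mutate(diff = d, index = idx),
      statistic = res$statistic,
      p_value = res$p_value,
      n_used = res$n_used,
      mean_index = mean(idx, na.rm = TRUE),
      tied = res$tied,
      method = res$method
    ),
    class = "devaluation_result"
  )
}

#' @export
print.devaluation_result <- function(x, ...) {
  cat(sprintf(
    "<devaluation_result> n = %d pairs (%d informative)\n  V = %s, p = %.4g [%s]\n  mean devaluation index = %.3f\n",
    nrow(x$pairs), x$n_used,
    format(x$statistic), x$p_value, x$method, x$mean_index
  ))
  if (x$tied) cat("  note: all pairs tied; p = 1 by convention\n")
  invisible(x)
}

#' Nonparametric multi-group comparison with Dunn posthoc tests
#'
#' Kruskal-Wallis omnibus rank test (tie-corrected, via
#' [stats::kruskal.test()]) followed by Dunn's pairwise z tests on mean
#' ranks with Bonferroni adjustment over all unordered pairs. Fully
#' degenerate data (all values identical) yield p = 1 by convention.
#'
#' @param data A data frame.
#' @param value,group Columns (unquoted) holding the per-subject values and
#'   group labels.
#' @param p_adjust Multiplicity adjustment for the posthoc p-values
#'   (default `"bonferroni"`; any [stats::p.adjust()] method).
#' @return A `group_comparison`: list with `omnibus` (tibble `statistic`,
#'   `df`, `p_value`) and `posthoc` (tibble `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`).
#' @export
group_compare <- function(data, value, group, p_adjust = "bonferroni") {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- droplevels(as.factor(rlang::eval_tidy(rlang::enquo(group), data)))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2)) stop("every group needs at least 2 observations", call. = FALSE)

  kw <- stats::kruskal.test(v, g)
  omnibus_p <- kw$p.value
  if (!is.finite(kw$statistic)) omnibus_p <- 1 # all values tied

  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tiecorr
  pairs <- utils::combn(levels(g), 2)
  z <- p_un <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    se <- sqrt(s2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[j] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p_un[j] <- if (se > 0) 2 * stats::pnorm(-abs(z[j])) else 1
  }
  structure(
    list(
      omnibus = tibble(
        statistic = unname(kw$statistic),
        df = unname(kw$parameter),
        p_value = omnibus_p
      ),
      posthoc = tibble(
        group1 = pairs[1, ], group2 = pairs[2, ],
        z = z, p_value = p_un,
        p_adjusted = pmin(1, stats::p.adjust(p_un, method = p_adjust))
      ),
      group_sizes = tibble(group = names(sizes), n = as.integer(sizes))
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> Kruskal-Wallis chi-sq = %.3f, df = %s, p = %.4g\n",
    x$omnibus$statistic, format(x$omnibus$df), x$omnibus$p_value
  ))
  print(x$posthoc)
  invisible(x)
}

#' Correct fluid consumption for evaporation
#'
#' Subtracts the mean evaporation loss measured in control cages (without
#' animals) from each raw consumption volume, clamping at zero.
#'
#' @param raw_ml Numeric vector of raw consumption volumes (mL).
#' @param control_cage_losses Numeric vector of evaporation losses from
#'   control cages (mL); at least one value.
#' @return A tibble: `raw_ml`, `corrected_ml`, `clamped` (logical, `TRUE`
#'   where the correction hit the zero floor).
#' @examples
#' normalize_evaporation(3.0, c(0.3, 0.5, 0.4, 0.4))
#' @export
normalize_evaporation <- function(raw_ml, control_cage_losses) {
  if (length(control_cage_losses) < 1) {
    stop("need at least one control measurement", call. = FALSE)
  }
  if (any(raw_ml < 0) || any(control_cage_losses < 0)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  loss <- mean(control_cage_losses)
  corrected <- pmax(0, raw_ml - loss)
  tibble(
    raw_ml = raw_ml,
    corrected_ml = corrected,
    clamped = raw_ml - loss < 0
  )
}
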