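# broom-style tidy()/glance() methods.

#' Tidy per-resample decoding metrics
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A tibble with one row per resample: `resample`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
tidy.decoding_result <- function(x, ...) {
  x$metrics
}

#' Summarise a decoding result in one row
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A one-row tibble of metric means and SDs plus protocol metadata.
#' @export
glance.decoding_result <- function(x, ...) {
  s <- x$summary
  out <- tibble(
    event_class = x$event_class,
    n_resamples = x$n_resamples, k = x$k, n_per_class = x$n_per_class
  )
  for (i in seq_len(nrow(s))) {
    out[[paste0("mean_", s$metric[i])]] <- s$mean[i]
    out[[paste0("sd_", s$metric[i])]] <- s$sd[i]
  }
  out
}

#' Tidy per-block means of a trial-progression fit
#'
#' @param x A `block_summary`.
#' @param ... Unused.
#' @return The `blocks` tibble: `block`, `n_events`, `mean_metric`.
#' @export
tidy.block_summary <- function(x, ...) {
  x$blocks
}

#' Summarise a trial-progression fit in one row
#'
#' @param x A `block_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `event_class`, `metric`, `slope`, `intercept`,
#'   `p_value`, `n_blocks`, `n_events`.
#' @export
glance.block_summary <- function(x, ...) {
  tibble(
    event_class = x$event_class, metric = x$metric,
    slope = x$slope, intercept = x$intercept, p_value = x$p_value,
    n_blocks = x$n_blocks, n_events = x$n_events
  )
}

#' Tidy the per-subject rows of a devaluation test
#'
#' @param x A `devaluation_result`.
#' @param ... Unused.
#' @return A tibble with `valued`, `devalued`, `diff`, `index` per subject.
#' @export
tidy.devaluation_result <- function(x, ...) {
  x$pairs
}

#' Summarise a devaluation test in one row
#'
#' @param x A `devaluation_result`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p_value`, `n_used`,
#'   `mean_index`, `tied`, `method`.
#' @export
glance.devaluation_result <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value, n_used = x$n_used,
    mean_index = x$mean_index, tied = x$tied, method = x$method
  )
}

#' Tidy the pairwise posthoc table of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The posthoc tibble: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$posthoc
}

#' Summarise the omnibus test of a group comparison in one row
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
glance.group_comparison <- function(x, ...) {
  x$omnibus
}
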