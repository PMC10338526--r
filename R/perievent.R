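# Peri-event alignment, class averages, decile-block trends and pointwise
# group comparison.

new_perievent_tbl <- function(df, fps, pre_s, post_s, n_dropped, condition_label) {
  tibble::new_tibble(
    df,
    nrow = nrow(df),
    class = "perievent_tbl",
    fps = fps,
    pre_s = pre_s,
    post_s = post_s,
    n_frames = round((pre_s + post_s) * fps),
    n_dropped = n_dropped,
    condition_label = condition_label
  )
}

#' Align dF/F snippets to behavioural events
#'
#' Extracts, for every classifiable behavioural event (active nose pokes and
#' magazine entries/exits, split by rewarded status), the dF/F frames in the
#' half-open window `[t_event - pre_s, t_event + post_s)`. The event frame
#' (first frame at or after the event time) sits at 0-based snippet index
#' `pre_s * fps`, so the default 2 s + 2 s window at 30 fps gives 120-frame
#' snippets with the event at index 60. Events whose window leaves the
#' defined part of the trace (including the warm-up `NA` frames) are dropped
#' and counted in the `n_dropped` attribute.
#'
#' @param dff A `dff_trace`.
#' @param events An `operant_session` or any data frame with `time_s`,
#'   `event_type`, `rewarded`, sorted by time.
#' @param pre_s,post_s Window half-widths in seconds (defaults 2 and 2).
#' @return A `perievent_tbl`: tibble with columns `event_class`,
#'   `event_time_s`, `ordinal` (position within its class) and `snippet`
#'   (list-column of numeric vectors), plus attributes `fps`, `pre_s`,
#'   `post_s`, `n_frames`, `n_dropped`, `condition_label`.
#' @export
extract_perievent <- function(dff, events, pre_s = 2, post_s = 2) {
  fps <- attr(dff, "fps")
  if (is.null(fps)) stop("`dff` must carry an `fps` attribute", call. = FALSE)
  if (pre_s <= 0 || post_s <= 0) stop("`pre_s` and `post_s` must be positive", call. = FALSE)
  if (is.unsorted(events$time_s)) stop("`events` must be sorted by time", call. = FALSE)
  v <- dff$dff
  n <- length(v)
  n_pre <- round(pre_s * fps)
  n_post <- round(post_s * fps)

  cls <- event_class_of(events$event_type, events$rewarded)
  keep <- !is.na(cls)
  times <- events$time_s[keep]
  cls <- cls[keep]

  i0 <- ceiling(times * fps - 1e-9) # 0-based index of the event frame
  lo <- i0 - n_pre
  hi <- i0 + n_post - 1
  in_range <- lo >= 0 & hi <= n - 1
  ok <- in_range
  ok[in_range] <- purrr::map2_lgl(
    lo[in_range], hi[in_range],
    function(a, b) !anyNA(v[(a + 1):(b + 1)])
  )
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no alignable events", call. = FALSE)

  snippets <- purrr::map2(lo[ok], hi[ok], function(a, b) v[(a + 1):(b + 1)])
  df <- tibble(
    event_class = cls[ok],
    event_time_s = times[ok],
    snippet = snippets
  )
  df <- df[order(df$event_time_s), , drop = FALSE]
  df$ordinal <- stats::ave(seq_len(nrow(df)), df$event_class, FUN = seq_along)
  df <- df[, c("event_class", "event_time_s", "ordinal", "snippet")]
  new_perievent_tbl(df, fps, pre_s, post_s, n_dropped, attr(dff, "condition_label"))
}

#' @export
print.perievent_tbl <- function(x, ...) {
  cat(sprintf(
    "<perievent_tbl> %d events x %d frames (%g fps; %d dropped)\n",
    nrow(x), attr(x, "n_frames"), attr(x, "fps"), attr(x, "n_dropped")
  ))
  NextMethod()
}

#' Pool peri-event tables across sessions
#'
#' Binds several `perievent_tbl`s (e.g. one per session of the same
#' condition) after checking that their window geometry matches. Ordinals
#' are recomputed over the pooled event order.
#'
#' @param pems A list of `perievent_tbl` objects.
#' @param ids Optional identifiers added as a `session` column.
#' @return A pooled `perievent_tbl`.
#' @export
bind_perievent <- function(pems, ids = seq_along(pems)) {
  stopifnot(length(pems) >= 1)
  a1 <- attributes(pems[[1]])
  for (p in pems[-1]) {
    if (!isTRUE(all.equal(attr(p, "fps"), a1$fps)) ||
      !isTRUE(all.equal(attr(p, "pre_s"), a1$pre_s)) ||
      !isTRUE(all.equal(attr(p, "post_s"), a1$post_s))) {
      stop("peri-event tables have mismatched window geometry", call. = FALSE)
    }
  }
  dfs <- purrr::map2(pems, ids, function(p, id) {
    d <- tibble::as_tibble(p)
    d$session <- id
    d
  })
  df <- dplyr::bind_rows(dfs)
  df$ordinal <- stats::ave(seq_len(nrow(df)), df$event_class, FUN = seq_along)
  new_perievent_tbl(
    df, a1$fps, a1$pre_s, a1$post_s,
    sum(purrr::map_int(pems, ~ attr(.x, "n_dropped"))),
    a1$condition_label
  )
}

pem_matrix <- function(pem, event_class = NULL) {
  d <- pem
  if (!is.null(event_class)) {
    if (!event_class %in% EVENT_CLASSES) {
      stop("unknown event class: ", event_class, call. = FALSE)
    }
    d <- d[d$event_class == event_class, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no events of class ", event_class, call. = FALSE)
  do.call(rbind, d$snippet)
}

pem_time_axis <- function(pem) {
  n_pre <- round(attr(pem, "pre_s") * attr(pem, "fps"))
  (seq_len(attr(pem, "n_frames")) - 1 - n_pre) / attr(pem, "fps")
}

#' Per-frame mean and SEM of one event class
#'
#' @param pem A `perievent_tbl`.
#' @param event_class One of the six peri-event class labels.
#' @return A `perievent_avg` tibble: `time_s` (0 = event), `mean`, `sem`
#'   (`NaN` for a single event), `n`.
#' @export
class_average <- function(pem, event_class) {
  m <- pem_matrix(pem, event_class)
  n <- nrow(m)
  sem <- if (n < 2) rep(NaN, ncol(m)) else apply(m, 2, stats::sd) / sqrt(n)
  tibble::new_tibble(
    tibble(
      time_s = pem_time_axis(pem),
      mean = colMeans(m),
      sem = sem,
      n = n
    ),
    nrow = ncol(m),
    class = "perievent_avg",
    event_class = event_class,
    condition_label = attr(pem, "condition_label")
  )
}

# Spec'd partition: block b (0-based) covers event indices
# floor(b * n / n_blocks) .. floor((b + 1) * n / n_blocks) - 1.
block_assignment <- function(n, n_blocks) {
  bounds <- floor(seq_len(n_blocks) * n / n_blocks)
  findInterval(seq_len(n) - 1, c(0, bounds), left.open = FALSE,
    rightmost.closed = FALSE
  )
}

event_change_metric <- function(pem, rows, metric) {
  n_pre <- round(attr(pem, "pre_s") * attr(pem, "fps"))
  n_frames <- attr(pem, "n_frames")
  purrr::map_dbl(rows$snippet, function(s) {
    pre <- s[seq_len(n_pre)]
    post <- s[(n_pre + 1):n_frames]
    switch(metric,
      post_minus_pre = mean(post) - mean(pre),
      peak = max(s),
      auc = sum(post - mean(pre)) / attr(pem, "fps")
    )
  })
}

#' Within-session trend of peri-event responses across decile blocks
#'
#' Orders the events of one class by time, partitions them into `n_blocks`
#' contiguous blocks of (near-)equal size representing 10% increments of the
#' session's events of that class, computes a per-event change metric
#' (default: mean post-event dF/F minus mean pre-event dF/F), and fits
#' ordinary least squares of the block-mean metric against block index.
#'
#' @param pem A `perievent_tbl`.
#' @param event_class One of the six class labels.
#' @param n_blocks Number of blocks (default 10).
#' @param metric `"post_minus_pre"` (default), `"peak"` or `"auc"`.
#' @return A `block_summary` object: list with `blocks` (tibble `block`,
#'   `n_events`, `mean_metric`), `slope`, `intercept`, `p_value` (two-sided
#'   on the slope), and metadata.
#' @export
blockwise_trend <- function(pem, event_class, n_blocks = 10,
                            metric = c("post_minus_pre", "peak", "auc")) {
  metric <- match.arg(metric)
  if (n_blocks < 2) stop("`n_blocks` must be at least 2", call. = FALSE)
  if (!event_class %in% EVENT_CLASSES) {
    stop("unknown event class: ", event_class, call. = FALSE)
  }
  rows <- pem[pem$event_class == event_class, , drop = FALSE]
  rows <- rows[order(rows$event_time_s), , drop = FALSE]
  n <- nrow(rows)
  if (n < n_blocks) {
    stop("fewer events (", n, ") than blocks (", n_blocks, ")", call. = FALSE)
  }
  vals <- event_change_metric(pem, rows, metric)
  blk <- block_assignment(n, n_blocks)
  blocks <- tibble(
    block = seq_len(n_blocks),
    n_events = as.integer(tabulate(blk, n_blocks)),
    mean_metric = as.numeric(tapply(vals, factor(blk, levels = seq_len(n_blocks)), mean))
  )
  fit <- stats::lm(mean_metric ~ block, data = blocks)
  coefs <- summary(fit)$coefficients
  structure(
    list(
      blocks = blocks,
      slope = unname(coefs["block", "Estimate"]),
      intercept = unname(coefs["(Intercept)", "Estimate"]),
      p_value = unname(coefs["block", "Pr(>|t|)"]),
      n_blocks = n_blocks,
      n_events = n,
      event_class = event_class,
      metric = metric,
      condition_label = attr(pem, "condition_label"),
      fit = fit
    ),
    class = "block_summary"
  )
}

#' @export
print.block_summary <- function(x, ...) {
  cat(sprintf(
    "<block_summary> %s (%s), %d events in %d blocks\n  slope %.4g (p = %.3g), intercept %.4g\n",
    x$event_class, x$metric, x$n_events, x$n_blocks,
    x$slope, x$p_value, x$intercept
  ))
  invisible(x)
}

#' Frame-wise comparison of two peri-event groups
#'
#' Runs a Welch two-sample t test at every frame, corrects the per-frame
#' p-values across frames with Benjamini-Hochberg, and returns maximal runs
#' of significant frames as time ranges. This is a lightweight stand-in for
#' a repeated-measures ANOVA + posthoc readout of where two condition
#' traces differ.
#'
#' @param pem_a,pem_b `perievent_tbl`s with identical window geometry.
#' @param event_class Optional class label to filter both tables first.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return A tibble of significant ranges: `start_frame`, `end_frame`
#'   (0-based, inclusive), `start_s`, `end_s`, `min_p_adj`. Zero rows when
#'   nothing is significant.
#' @export
pointwise_group_compare <- function(pem_a, pem_b, event_class = NULL,
                                    alpha = 0.05) {
  for (nm in c("fps", "pre_s", "post_s")) {
    if (!isTRUE(all.equal(attr(pem_a, nm), attr(pem_b, nm)))) {
      stop("peri-event tables have mismatched window geometry", call. = FALSE)
    }
  }
  ma <- pem_matrix(pem_a, event_class)
  mb <- pem_matrix(pem_b, event_class)
  if (nrow(ma) < 2 || nrow(mb) < 2) {
    stop("each group needs at least 2 events", call. = FALSE)
  }
  p <- vapply(seq_len(ncol(ma)), function(j) {
    tryCatch(stats::t.test(ma[, j], mb[, j])$p.value, error = function(e) NaN)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p_adj) & p_adj < alpha
  fps <- attr(pem_a, "fps")
  n_pre <- round(attr(pem_a, "pre_s") * fps)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  starts <- starts[r$values]
  ends <- ends[r$values]
  tibble(
    start_frame = starts - 1L,
    end_frame = ends - 1L,
    start_s = (starts - 1 - n_pre) / fps,
    end_s = (ends - 1 - n_pre) / fps,
    min_p_adj = purrr::map2_dbl(starts, ends, function(a, b) min(p_adj[a:b]))
  )
}
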