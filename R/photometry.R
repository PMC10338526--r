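# Three-stage dF/F computation and supra-threshold calcium event detection.

#' Parameters of the three-stage dF/F computation
#'
#' Stage 1 averages the raw fluorescence over a sliding window and takes the
#' baseline as the minimum of that average over a window preceding each
#' frame; stage 2 forms `dF/F = (F_RAW - F_BASELINE) / F_BASELINE`; stage 3
#' smooths with an exponentially weighted moving window of time constant
#' `tau_s` and width `smooth_width_s`.
#'
#' @param avg_window_s Sliding-mean width in seconds (default 0.75).
#' @param baseline_window_s Preceding-minimum window in seconds (default 3).
#' @param tau_s Smoothing time constant in seconds (default 0.2).
#' @param smooth_width_s Smoothing window width in seconds (default 1).
#' @param centered_avg If `TRUE` the stage-1 mean is centered on the frame;
#'   the default is causal (trailing window including the current frame).
#' @param smooth If `FALSE`, stage 3 is skipped and the unsmoothed dF/F is
#'   returned.
#' @return A `dff_params` object.
#' @export
dff_params <- function(avg_window_s = 0.75,
                       baseline_window_s = 3,
                       tau_s = 0.2,
                       smooth_width_s = 1,
                       centered_avg = FALSE,
                       smooth = TRUE) {
  vals <- c(avg_window_s, baseline_window_s, tau_s, smooth_width_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all dF/F window parameters must be strictly positive", call. = FALSE)
  }
  if (baseline_window_s < avg_window_s) {
    stop("`baseline_window_s` must be at least `avg_window_s`", call. = FALSE)
  }
  structure(
    list(
      avg_window_s = avg_window_s, baseline_window_s = baseline_window_s,
      tau_s = tau_s, smooth_width_s = smooth_width_s,
      centered_avg = isTRUE(centered_avg), smooth = isTRUE(smooth)
    ),
    class = "dff_params"
  )
}

# Windowed mean via cumulative sums; causal windows span (i - w + 1):i,
# centered windows are clipped at the edges.
sliding_mean <- function(x, w, centered = FALSE) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  if (centered) {
    lo <- pmax(1, i - floor((w - 1) / 2))
    hi <- pmin(n, i + ceiling((w - 1) / 2))
  } else {
    lo <- pmax(1, i - w + 1)
    hi <- i
  }
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Compute dF/F from a raw fluorescence trace
#'
#' Implements the three-stage computation described in [dff_params()].
#' The baseline window strictly precedes the current frame, so the first
#' `baseline_window_s` seconds of the trace have undefined dF/F (`NA`);
#' those warm-up frames are excluded from event detection and peri-event
#' extraction downstream.
#'
#' @param raw A `raw_trace` (or any tibble with `time_s`, `fluorescence` plus
#'   an `fps` attribute).
#' @param params A [dff_params()].
#' @param keep_intermediates If `TRUE`, the returned tibble also carries
#'   `f_avg` and `f_baseline` columns.
#' @return A `dff_trace`: tibble with columns `time_s`, `dff` and attributes
#'   `fps`, `params` (plus `condition_label` carried over when present).
#' @examples
#' s <- simulate_session(schedule_spec("RR", 5), agent_params(0.5), seed = 1)
#' tr <- generate_trace(s, neural_params(), seed = 2)
#' d <- compute_dff(tr)
#' @export
compute_dff <- function(raw, params = dff_params(), keep_intermediates = FALSE) {
  fps <- attr(raw, "fps")
  if (is.null(fps)) stop("`raw` must carry an `fps` attribute", call. = FALSE)
  x <- raw$fluorescence
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("non-positive fluorescence", call. = FALSE)
  }
  n <- length(x)
  wb <- max(1L, round(params$baseline_window_s * fps))
  if (n <= wb) stop("trace shorter than the baseline window", call. = FALSE)
  wa <- max(1L, round(params$avg_window_s * fps))

  f_avg <- sliding_mean(x, wa, centered = params$centered_avg)

  # Baseline: min of F_AVG over the wb frames strictly preceding each frame.
  rollmin <- data.table::frollapply(f_avg, wb, min, align = "right")
  f_base <- c(NA_real_, rollmin[-n])
  dff <- (x - f_base) / f_base

  if (params$smooth) {
    m <- max(1L, round(params$smooth_width_s * fps))
    wgt <- exp(-(seq_len(m) - 1) / (params$tau_s * fps))
    defined <- !is.na(dff)
    z <- ifelse(defined, dff, 0)
    pad <- rep(0, m - 1)
    num <- stats::filter(c(pad, z), wgt, sides = 1)[m:(n + m - 1)]
    den <- stats::filter(c(pad, as.numeric(defined)), wgt, sides = 1)[m:(n + m - 1)]
    sm <- ifelse(defined, as.numeric(num) / as.numeric(den), NA_real_)
    dff <- sm
  }

  out <- tibble(time_s = raw$time_s, dff = dff)
  if (keep_intermediates) {
    out$f_avg <- f_avg
    out$f_baseline <- f_base
  }
  tibble::new_tibble(
    out,
    nrow = n,
    class = "dff_trace",
    fps = fps,
    params = params,
    condition_label = attr(raw, "condition_label"),
    duration_s = attr(raw, "duration_s")
  )
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf(
    "<dff_trace> %d frames at %g fps (%d warm-up NA)\n",
    nrow(x), attr(x, "fps"), sum(is.na(x$dff))
  ))
  NextMethod()
}

#' Detect supra-threshold calcium events
#'
#' Events are maximal runs of consecutive frames with `dff >= threshold`;
#' undefined (`NA`) frames break runs. The default 2% threshold follows the
#' convention of counting calcium transients exceeding dF/F = 0.02 on the
#' smoothed trace.
#'
#' @param dff A `dff_trace`.
#' @param threshold Positive dF/F threshold (default 0.02).
#' @return A tibble with one row per event: `onset_frame` (0-based),
#'   `onset_s`, `duration_s`, `peak_dff`.
#' @export
detect_events <- function(dff, threshold = 0.02) {
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  v <- dff$dff
  if (all(is.na(v))) stop("all dF/F values are undefined", call. = FALSE)
  fps <- attr(dff, "fps")
  above <- !is.na(v) & v >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  starts <- starts[keep]
  ends <- ends[keep]
  tibble(
    onset_frame = starts - 1L,
    onset_s = (starts - 1) / fps,
    duration_s = (ends - starts + 1) / fps,
    peak_dff = purrr::map2_dbl(starts, ends, function(a, b) max(v[a:b]))
  )
}

#' Summarise detected calcium events
#'
#' @param events Event table from [detect_events()].
#' @param trace_duration_s Duration of the underlying trace in seconds.
#' @return A one-row tibble: `n_events`, `events_per_min`, `mean_duration_s`
#'   (`NaN` when there are no events).
#' @export
summarize_events <- function(events, trace_duration_s) {
  if (!is.numeric(trace_duration_s) || trace_duration_s <= 0) {
    stop("`trace_duration_s` must be positive", call. = FALSE)
  }
  n <- nrow(events)
  tibble(
    n_events = n,
    events_per_min = n / (trace_duration_s / 60),
    mean_duration_s = if (n == 0) NaN else mean(events$duration_s)
  )
}
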