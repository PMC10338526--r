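# Independent reference implementations used as oracles. These deliberately
# recompute everything frame by frame / by full enumeration, sharing no code
# with the package internals.

# Naive per-frame three-stage dF/F (causal windows; baseline excludes the
# current frame; smoothing renormalised over defined frames).
naive_dff <- function(x, fps, avg_window_s = 0.75, baseline_window_s = 3,
                      tau_s = 0.2, smooth_width_s = 1, smooth = TRUE) {
  n <- length(x)
  wa <- max(1, round(avg_window_s * fps))
  wb <- max(1, round(baseline_window_s * fps))
  f_avg <- vapply(seq_len(n), function(i) mean(x[max(1, i - wa + 1):i]), 0)
  dff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - wb < 1) next
    base <- min(f_avg[(i - wb):(i - 1)])
    dff[i] <- (x[i] - base) / base
  }
  if (!smooth) {
    return(dff)
  }
  m <- max(1, round(smooth_width_s * fps))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(dff[i])) next
    ks <- 0:min(m - 1, i - 1)
    vals <- dff[i - ks]
    w <- exp(-(ks / fps) / tau_s)
    ok <- !is.na(vals)
    out[i] <- sum(w[ok] * vals[ok]) / sum(w[ok])
  }
  out
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# patterns (zeros already removed by the caller). Feasible for n <= 12.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w <- apply(signs, 1, function(s) sum(r[s]))
  ple <- mean(w <= v_obs + 1e-9)
  pge <- mean(w >= v_obs - 1e-9)
  min(1, 2 * min(ple, pge))
}

# Poke counts of an extinction session.
count_active_pokes <- function(session) {
  sum(session$event_type == "nose_poke_active")
}

# Minimal raw_trace wrapper around a numeric vector.
raw_trace_from_acc <- function(x, fps = 30) {
  tibble::new_tibble(
    tibble::tibble(time_s = (seq_along(x) - 1) / fps, fluorescence = x),
    nrow = length(x), class = "raw_trace", fps = fps,
    condition_label = NA_character_, duration_s = (length(x) - 1) / fps
  )
}
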