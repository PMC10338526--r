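# Synthetic GCaMP-like fluorescence trace generation.

#' Default peri-event transient amplitudes by condition and event class
#'
#' Encodes the condition orderings used throughout the package's synthetic
#' recordings: RI above RR around nose pokes (rewarded and unrewarded) and
#' rewarded magazine entry, RR above RI at rewarded magazine exit, and no
#' difference for unrewarded magazine entry/exit. Amplitudes are in the same
#' arbitrary units as the baseline fluorescence `f0`; at the default
#' `f0 = 100` they correspond to peak dF/F transients of roughly 2-6%.
#'
#' @param separation Scales the RI-minus-RR gap for every event class;
#'   `separation = 0` makes the two conditions identical (a null generator),
#'   1 is the default study condition.
#' @return A tibble with columns `condition`, `event_class`, `amplitude`.
#' @export
default_event_amplitudes <- function(separation = 1) {
  rr <- c(
    "NP R+" = 3, "NP R-" = 2.5,
    "M_entry R+" = 3, "M_entry R-" = 3,
    "M_exit R+" = 5, "M_exit R-" = 2
  )
  delta <- c(
    "NP R+" = 3, "NP R-" = 2.5,
    "M_entry R+" = 3, "M_entry R-" = 0,
    "M_exit R+" = -2.5, "M_exit R-" = 0
  )
  dplyr::bind_rows(
    tibble(condition = "RR", event_class = names(rr), amplitude = unname(rr)),
    tibble(
      condition = "RI", event_class = names(rr),
      amplitude = unname(rr + separation * delta)
    )
  )
}

#' Parameters of the synthetic fluorescence generator
#'
#' The generated raw trace is
#' `F_RAW(t) = f0 + sum_events a_e * K(t - t_e) + noise`, where `K` is a
#' double-exponential calcium-indicator kernel normalised to peak 1
#' (GCaMP6s-like defaults: 0.2 s rise, 1.0 s decay) and the per-event
#' amplitude `a_e` is the class/condition base amplitude plus the event's
#' decile-block index (0-9, by ordinal position within its class) times a
#' per-block drift slope. Noise is i.i.d. Gaussian per frame; output is
#' clipped to a small positive floor so fluorescence stays positive.
#'
#' @param f0 Baseline fluorescence (arbitrary units, positive).
#' @param kernel_rise_s,kernel_decay_s Kernel time constants (s); decay must
#'   exceed rise.
#' @param event_amplitudes Tibble `condition`/`event_class`/`amplitude`; see
#'   [default_event_amplitudes()]. Events without a matching row contribute
#'   no transient.
#' @param drift_slope_per_block Optional tibble `condition`/`event_class`/
#'   `slope`: per-decile amplitude increment (same units as `amplitude`).
#'   `NULL` means no within-session drift.
#' @param noise_sd Gaussian noise SD per frame (arbitrary units).
#' @param fps Frames per second (default 30).
#' @return A `neural_params` object.
#' @export
neural_params <- function(f0 = 100,
                          kernel_rise_s = 0.2,
                          kernel_decay_s = 1,
                          event_amplitudes = default_event_amplitudes(),
                          drift_slope_per_block = NULL,
                          noise_sd = 0.5,
                          fps = 30) {
  if (f0 <= 0) stop("`f0` must be positive", call. = FALSE)
  if (!(kernel_decay_s > kernel_rise_s && kernel_rise_s > 0)) {
    stop("need kernel_decay_s > kernel_rise_s > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  stopifnot(all(c("condition", "event_class", "amplitude") %in% names(event_amplitudes)))
  if (!is.null(drift_slope_per_block)) {
    stopifnot(all(c("condition", "event_class", "slope") %in% names(drift_slope_per_block)))
  }
  structure(
    list(
      f0 = f0, kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
      event_amplitudes = event_amplitudes,
      drift_slope_per_block = drift_slope_per_block,
      noise_sd = noise_sd, fps = fps
    ),
    class = "neural_params"
  )
}

# Lag from event onset to the kernel peak (closed form for the normalised
# double exponential).
kernel_peak_lag <- function(rise, decay) {
  rise * decay / (decay - rise) * log(decay / rise)
}

# Per-event amplitudes: base amplitude by (condition, class) plus decile
# drift. Block index is 0-based over 10 deciles of the event's ordinal
# position within its class.
event_amplitudes_for <- function(ev, condition, params) {
  amp_tbl <- params$event_amplitudes[params$event_amplitudes$condition %in% condition, ]
  base <- amp_tbl$amplitude[match(ev$event_class, amp_tbl$event_class)]
  base[is.na(base)] <- 0
  ord <- stats::ave(seq_len(nrow(ev)), ev$event_class, FUN = seq_along)
  ncl <- stats::ave(seq_len(nrow(ev)), ev$event_class, FUN = length)
  block <- floor((ord - 1) * 10 / ncl)
  slope <- rep(0, nrow(ev))
  if (!is.null(params$drift_slope_per_block)) {
    sl <- params$drift_slope_per_block
    sl <- sl[sl$condition %in% condition, ]
    m <- sl$slope[match(ev$event_class, sl$event_class)]
    slope <- ifelse(is.na(m), 0, m)
  }
  base + block * slope
}

#' Generate a synthetic raw fluorescence trace for a session
#'
#' @param session An `operant_session` (its `condition_label` attribute keys
#'   the amplitude table).
#' @param params A [neural_params()].
#' @param seed Optional seed; identical seeds give bit-identical traces.
#' @param max_duration_s Guard against accidentally huge traces (default 2 h).
#' @return A `raw_trace`: tibble with columns `time_s`, `fluorescence`
#'   (frames at `0, 1/fps, ...`) and attributes `fps`, `params`,
#'   `condition_label`, `duration_s`.
#' @export
generate_trace <- function(session, params = neural_params(), seed = NULL,
                           max_duration_s = 7200) {
  if (params$fps <= 0) stop("`fps` must be positive", call. = FALSE)
  dur <- attr(session, "duration_s")
  if (is.null(dur)) dur <- max(session$time_s, 0)
  if (dur > max_duration_s) {
    stop("session duration exceeds `max_duration_s`", call. = FALSE)
  }
  fps <- params$fps
  n <- floor(dur * fps) + 1
  cond <- attr(session, "condition_label")
  with_seed_(seed, {
    sig <- numeric(n)
    ev <- data.frame(
      time_s = session$time_s,
      event_class = event_class_of(session$event_type, session$rewarded),
      stringsAsFactors = FALSE
    )
    ev <- ev[!is.na(ev$event_class), , drop = FALSE]
    if (nrow(ev)) {
      kr <- params$kernel_rise_s
      kd <- params$kernel_decay_s
      tp <- kernel_peak_lag(kr, kd)
      peak <- exp(-tp / kd) - exp(-tp / kr)
      L <- ceiling(10 * kd * fps)
      amps <- event_amplitudes_for(ev, cond, params)
      for (e in seq_len(nrow(ev))) {
        if (amps[e] == 0) next
        i0 <- ceiling(ev$time_s[e] * fps - 1e-9)
        if (i0 > n - 1) next
        idx <- i0:min(i0 + L, n - 1)
        tt <- idx / fps - ev$time_s[e]
        sig[idx + 1] <- sig[idx + 1] +
          amps[e] * (exp(-tt / kd) - exp(-tt / kr)) / peak
      }
    }
    raw <- params$f0 + sig
    if (params$noise_sd > 0) raw <- raw + stats::rnorm(n, 0, params$noise_sd)
    raw <- pmax(raw, 1e-6)
    tibble::new_tibble(
      tibble(time_s = (seq_len(n) - 1) / fps, fluorescence = raw),
      nrow = n,
      class = "raw_trace",
      fps = fps,
      params = params,
      condition_label = cond,
      duration_s = dur,
      seed = seed
    )
  })
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf(
    "<raw_trace> %d frames at %g fps (%.1f s)\n",
    nrow(x), attr(x, "fps"), nrow(x) / attr(x, "fps")
  ))
  NextMethod()
}
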