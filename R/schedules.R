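# Operant schedule engines and behavioural agent simulation.

#' Define an operant reinforcement schedule
#'
#' @param kind One of `"FR"` (fixed ratio), `"RR"` (random ratio),
#'   `"RI"` (random interval) or `"EXTINCTION"` (no reinforcement).
#' @param value Schedule parameter: responses per reinforcement for FR/RR,
#'   mean armed interval in seconds for RI. Ignored for EXTINCTION.
#' @param session_cap_s Session time cap in seconds (default 1800, i.e.
#'   30 min). May be `Inf` for calibration runs.
#' @param reward_cap Maximum number of reinforcements per session
#'   (default 60). May be `Inf`.
#' @return A `schedule_spec` object.
#' @examples
#' schedule_spec("RI", 120)
#' schedule_spec("RR", 20, session_cap_s = Inf, reward_cap = 1000)
#' @export
schedule_spec <- function(kind = c("FR", "RR", "RI", "EXTINCTION"),
                          value = NULL,
                          session_cap_s = 1800,
                          reward_cap = 60) {
  kind <- match.arg(kind)
  if (kind != "EXTINCTION") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1 || value <= 0) {
      stop("`value` must be a single positive number for ", kind, " schedules",
        call. = FALSE
      )
    }
  } else {
    value <- NA_real_
  }
  if (!is.numeric(session_cap_s) || session_cap_s <= 0) {
    stop("`session_cap_s` must be positive", call. = FALSE)
  }
  if (!is.numeric(reward_cap) || reward_cap <= 0) {
    stop("`reward_cap` must be positive", call. = FALSE)
  }
  structure(
    list(
      kind = kind, value = as.numeric(value),
      session_cap_s = as.numeric(session_cap_s),
      reward_cap = reward_cap
    ),
    class = "schedule_spec"
  )
}

#' @export
print.schedule_spec <- function(x, ...) {
  v <- if (is.na(x$value)) "" else x$value
  cat(sprintf(
    "<schedule_spec> %s%s (caps: %s s / %s rewards)\n",
    x$kind, v, format(x$session_cap_s), format(x$reward_cap)
  ))
  invisible(x)
}

#' Define a simulated behavioural agent
#'
#' The agent responds as independent homogeneous Poisson processes per event
#' type (or on a fixed grid when `deterministic = TRUE`). After a reinforced
#' poke the agent collects the reward at the magazine after a fixed latency,
#' dwelling for an exponentially distributed time.
#'
#' @param nose_poke_rate_hz Rate of active-hole nose pokes (Hz).
#' @param inactive_rate_hz Rate of inactive-hole pokes (Hz).
#' @param magazine_check_rate_hz Rate of unrewarded magazine entries (Hz).
#' @param magazine_dwell_s Mean magazine dwell time per entry (s).
#' @param devaluation_factor Multiplier in `[0, 1]` applied to
#'   `nose_poke_rate_hz` in the devalued extinction condition. A
#'   goal-directed agent has a factor below 1; a habitual agent has 1.
#' @param deterministic If `TRUE`, active pokes occur on a regular grid at
#'   `nose_poke_rate_hz` instead of a Poisson process.
#' @return An `agent_params` object.
#' @export
agent_params <- function(nose_poke_rate_hz = 0.5,
                         inactive_rate_hz = 0.05,
                         magazine_check_rate_hz = 0.1,
                         magazine_dwell_s = 2,
                         devaluation_factor = 1,
                         deterministic = FALSE) {
  rates <- c(nose_poke_rate_hz, inactive_rate_hz, magazine_check_rate_hz)
  if (any(!is.finite(rates) & rates != Inf) || any(rates < 0)) {
    stop("agent rates must be non-negative", call. = FALSE)
  }
  if (magazine_dwell_s <= 0) stop("`magazine_dwell_s` must be positive", call. = FALSE)
  if (devaluation_factor < 0 || devaluation_factor > 1) {
    stop("`devaluation_factor` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      nose_poke_rate_hz = nose_poke_rate_hz,
      inactive_rate_hz = inactive_rate_hz,
      magazine_check_rate_hz = magazine_check_rate_hz,
      magazine_dwell_s = magazine_dwell_s,
      devaluation_factor = devaluation_factor,
      deterministic = isTRUE(deterministic)
    ),
    class = "agent_params"
  )
}

# Event times of a homogeneous Poisson process on [0, horizon].
poisson_times <- function(rate, horizon) {
  if (rate <= 0 || horizon <= 0) {
    return(numeric(0))
  }
  out <- numeric(0)
  cur <- 0
  repeat {
    n <- max(16, ceiling(rate * (horizon - cur) * 1.2 + 10))
    out <- c(out, cur + cumsum(stats::rexp(n, rate)))
    cur <- out[length(out)]
    if (cur > horizon) break
  }
  out[out <= horizon]
}

active_poke_times <- function(agent, horizon) {
  rate <- agent$nose_poke_rate_hz
  if (rate <= 0 || horizon <= 0) {
    return(numeric(0))
  }
  if (agent$deterministic) {
    seq(1 / rate, horizon, by = 1 / rate)
  } else {
    poisson_times(rate, horizon)
  }
}

# Indices of reinforced pokes under a random-interval schedule: a reward is
# armed at a random delay after the previous reward delivery, and the first
# active poke at/after the arming time is reinforced.
ri_reward_indices <- function(pokes, value, arming) {
  draw <- switch(arming,
    exponential = function() stats::rexp(1, 1 / value),
    uniform = function() stats::runif(1, 0, 2 * value)
  )
  rew <- integer(0)
  last <- 0
  n <- length(pokes)
  repeat {
    arm <- last + draw()
    i <- findInterval(arm, pokes)
    if (i < 1 || pokes[i] < arm) i <- i + 1
    if (i > n) break
    rew <- c(rew, i)
    last <- pokes[i]
  }
  rew
}

new_operant_session <- function(events, schedule, agent, duration_s, n_rewards,
                                termination, condition_label, seed = NULL) {
  tibble::new_tibble(
    events,
    nrow = nrow(events),
    class = "operant_session",
    schedule = schedule,
    agent = agent,
    duration_s = duration_s,
    n_rewards = n_rewards,
    termination = termination,
    condition_label = condition_label,
    seed = seed
  )
}

#' Simulate one operant session
#'
#' Generates a timestamped behavioural event stream under a reinforcement
#' schedule. Random-ratio (RR) schedules reinforce each active poke
#' independently with probability `1/value`; random-interval (RI) schedules
#' arm a reward at an exponentially distributed delay (mean `value` seconds)
#' after the previous reward delivery and reinforce the first active poke at
#' or after arming. Reinforced pokes are followed by a rewarded magazine
#' entry/exit pair (fixed approach latency, exponential dwell). The session
#' stops at whichever binds first of the time cap and the reinforcement cap.
#'
#' @param schedule A [schedule_spec()].
#' @param agent An [agent_params()].
#' @param seed Optional integer seed; identical seeds give identical sessions.
#' @param condition_label Optional `"RR"`/`"RI"` label for downstream decoding;
#'   defaults to the schedule kind where that is RR or RI.
#' @param ri_arming Distribution of RI arming delays: `"exponential"`
#'   (memoryless, the default) or `"uniform"` on `(0, 2 * value)`; both have
#'   mean `value`.
#' @param collect_latency_s Latency from reinforced poke to the rewarded
#'   magazine entry (s).
#' @return An `operant_session`: a tibble of events with columns `time_s`,
#'   `event_type`, `rewarded` and attributes `schedule`, `duration_s`,
#'   `n_rewards`, `termination` (`"time_cap"` or `"reward_cap"`) and
#'   `condition_label`.
#' @examples
#' s <- simulate_session(schedule_spec("RR", 2), agent_params(2, deterministic = TRUE), seed = 1)
#' session_summary(s)
#' @export
simulate_session <- function(schedule, agent, seed = NULL,
                             condition_label = NULL,
                             ri_arming = c("exponential", "uniform"),
                             collect_latency_s = 1) {
  if (!inherits(schedule, "schedule_spec")) stop("`schedule` must be a schedule_spec", call. = FALSE)
  if (!inherits(agent, "agent_params")) stop("`agent` must be agent_params", call. = FALSE)
  ri_arming <- match.arg(ri_arming)
  kind <- schedule$kind
  cap_t <- schedule$session_cap_s
  cap_r <- schedule$reward_cap
  if (!is.finite(cap_t) && (kind == "EXTINCTION" || agent$nose_poke_rate_hz <= 0)) {
    stop("degenerate agent: session cannot terminate (no time cap and no reinforceable responding)",
      call. = FALSE
    )
  }
  if (!is.finite(cap_t) && !is.finite(cap_r)) {
    stop("at least one of `session_cap_s` and `reward_cap` must be finite",
      call. = FALSE
    )
  }
  if (is.null(condition_label)) {
    condition_label <- switch(kind,
      RR = "RR", FR = "RR", RI = "RI", NA_character_
    )
  }

  with_seed_(seed, {
    horizon <- if (is.finite(cap_t)) {
      cap_t
    } else {
      per_reward <- switch(kind,
        RI = schedule$value + 2 / max(agent$nose_poke_rate_hz, 1e-6),
        schedule$value / max(agent$nose_poke_rate_hz, 1e-6)
      )
      cap_r * per_reward * 1.3 + 60
    }

    repeat {
      pokes <- active_poke_times(agent, horizon)
      rewarded <- logical(length(pokes))
      if (length(pokes) && kind != "EXTINCTION") {
        if (kind == "FR") {
          rewarded[seq_along(pokes) %% schedule$value == 0] <- TRUE
        } else if (kind == "RR") {
          rewarded <- if (schedule$value == 1) {
            rep(TRUE, length(pokes))
          } else {
            stats::runif(length(pokes)) < 1 / schedule$value
          }
        } else { # RI
          rewarded[ri_reward_indices(pokes, schedule$value, ri_arming)] <- TRUE
        }
      }
      if (is.finite(cap_t) || sum(rewarded) >= cap_r) break
      horizon <- horizon * 2
    }

    # Truncate reinforcements at the reward cap.
    rew_idx <- which(rewarded)
    capped <- length(rew_idx) >= cap_r && pokes[rew_idx[cap_r]] <= cap_t
    if (length(rew_idx) > cap_r) {
      rewarded[rew_idx[-seq_len(cap_r)]] <- FALSE
      rew_idx <- rew_idx[seq_len(cap_r)]
    }
    rt <- pokes[rew_idx]

    # Reward collection: rewarded magazine entry/exit pair per delivery.
    entry <- rt + collect_latency_s
    exit <- entry + stats::rexp(length(entry), 1 / agent$magazine_dwell_s)

    end <- if (capped) min(cap_t, exit[length(exit)]) else cap_t
    termination <- if (capped) "reward_cap" else "time_cap"

    # Unrewarded magazine checks and inactive pokes.
    chk <- poisson_times(agent$magazine_check_rate_hz, end)
    chk_exit <- chk + stats::rexp(length(chk), 1 / agent$magazine_dwell_s)
    inact <- poisson_times(agent$inactive_rate_hz, end)

    ev <- dplyr::bind_rows(
      tibble(time_s = pokes, event_type = "nose_poke_active", rewarded = rewarded),
      tibble(time_s = inact, event_type = "nose_poke_inactive", rewarded = FALSE),
      tibble(time_s = rt, event_type = "reward_delivery", rewarded = TRUE),
      tibble(time_s = entry, event_type = "magazine_entry", rewarded = TRUE),
      tibble(time_s = exit, event_type = "magazine_exit", rewarded = TRUE),
      tibble(time_s = chk, event_type = "magazine_entry", rewarded = FALSE),
      tibble(time_s = chk_exit, event_type = "magazine_exit", rewarded = FALSE)
    )
    ev <- ev[ev$time_s <= end, , drop = FALSE]
    prio <- c(
      nose_poke_active = 1, nose_poke_inactive = 1,
      reward_delivery = 2, magazine_entry = 3, magazine_exit = 4
    )
    ev <- ev[order(ev$time_s, prio[ev$event_type]), , drop = FALSE]

    new_operant_session(
      ev, schedule, agent,
      duration_s = end,
      n_rewards = sum(ev$event_type == "reward_delivery"),
      termination = termination,
      condition_label = condition_label,
      seed = seed
    )
  })
}

#' @export
print.operant_session <- function(x, ...) {
  sch <- attr(x, "schedule")
  v <- if (is.na(sch$value)) "" else sch$value
  cat(sprintf(
    "<operant_session> %s%s | %.1f s | %d rewards | terminated by %s\n",
    sch$kind, v, attr(x, "duration_s"), attr(x, "n_rewards"),
    attr(x, "termination")
  ))
  NextMethod()
}

#' Summarise an operant session
#'
#' @param session An `operant_session`.
#' @return A one-row tibble with schedule, counts and termination cause.
#' @export
session_summary <- function(session) {
  sch <- attr(session, "schedule")
  tibble(
    schedule_kind = sch$kind,
    schedule_value = sch$value,
    condition_label = attr(session, "condition_label"),
    duration_s = attr(session, "duration_s"),
    n_rewards = attr(session, "n_rewards"),
    n_active_pokes = sum(session$event_type == "nose_poke_active"),
    n_inactive_pokes = sum(session$event_type == "nose_poke_inactive"),
    termination = attr(session, "termination")
  )
}

#' Simulate a training curriculum
#'
#' Produces the ordered stage progression used to shape goal-directed
#' (RR track: RR2 1-2 days, RR5 2-3, RR10 2-3, RR20 2-3) or habitual
#' (RI track: RI30 2 days, RI60 2-3, RI120 4) responding. Day counts are
#' configurable within those ranges; the defaults use the minimum days.
#'
#' @param kind `"RR_track"` or `"RI_track"`.
#' @param agent An [agent_params()].
#' @param seed Optional master seed; per-session sub-seeds are derived from it.
#' @param days Optional integer vector of days per stage (length 4 for RR,
#'   3 for RI), each within the permitted range.
#' @param session_cap_s,reward_cap Session caps passed to every stage.
#' @return A list of `operant_session` objects, one per training day.
#' @export
simulate_curriculum <- function(kind = c("RR_track", "RI_track"), agent,
                                seed = NULL, days = NULL,
                                session_cap_s = 1800, reward_cap = 60) {
  kind <- match.arg(kind)
  stages <- if (kind == "RI_track") {
    list(kind = "RI", value = c(30, 60, 120), min = c(2, 2, 4), max = c(2, 3, 4))
  } else {
    list(kind = "RR", value = c(2, 5, 10, 20), min = c(1, 2, 2, 2), max = c(2, 3, 3, 3))
  }
  if (is.null(days)) days <- stages$min
  if (length(days) != length(stages$value) || any(days < stages$min) ||
    any(days > stages$max)) {
    stop("`days` must give one value per stage within the permitted ranges",
      call. = FALSE
    )
  }
  values <- rep(stages$value, days)
  if (length(values) == 0) stop("empty curriculum", call. = FALSE)
  with_seed_(seed, {
    seeds <- if (is.null(seed)) vector("list", length(values)) else as.list(derive_seeds(length(values)))
    purrr::map2(values, seeds, function(v, s) {
      simulate_session(
        schedule_spec(stages$kind, v, session_cap_s, reward_cap),
        agent,
        seed = s
      )
    })
  })
}

#' Simulate one nonreinforced devaluation extinction session
#'
#' Runs an EXTINCTION session (responses never reinforced). In the devalued
#' condition the agent's nose-poke rate is multiplied by its
#' `devaluation_factor`; a goal-directed agent (factor below 1) reduces
#' responding while a habitual agent (factor 1) does not.
#'
#' @param agent An [agent_params()].
#' @param condition `"valued"` or `"devalued"`.
#' @param duration_s Session duration in seconds (default 600, i.e. 10 min).
#' @param seed Optional seed.
#' @return An `operant_session` with an additional `condition` attribute.
#' @export
simulate_devaluation_pair <- function(agent,
                                      condition = c("valued", "devalued"),
                                      duration_s = 600, seed = NULL) {
  condition <- match.arg(condition)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  a <- agent
  if (condition == "devalued") {
    a$nose_poke_rate_hz <- a$nose_poke_rate_hz * a$devaluation_factor
  }
  s <- simulate_session(
    schedule_spec("EXTINCTION", session_cap_s = duration_s, reward_cap = 1),
    a,
    seed = seed
  )
  attr(s, "condition") <- condition
  s
}

#' Simulate a cohort of paired valued/devalued extinction tests
#'
#' Convenience wrapper running [simulate_devaluation_pair()] in both
#' conditions for `n_subjects` independent agents and counting active nose
#' pokes, in the paired format expected by [devaluation_test()].
#'
#' @param n_subjects Number of subjects.
#' @param agent An [agent_params()] shared by all subjects.
#' @param duration_s Extinction session duration (s).
#' @param seed Optional master seed.
#' @return A tibble with columns `subject`, `valued`, `devalued`.
#' @export
simulate_devaluation_cohort <- function(n_subjects, agent, duration_s = 600,
                                        seed = NULL) {
  stopifnot(n_subjects >= 1)
  with_seed_(seed, {
    seeds <- if (is.null(seed)) {
      replicate(2 * n_subjects, NULL, simplify = FALSE)
    } else {
      as.list(derive_seeds(2 * n_subjects))
    }
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      v <- simulate_devaluation_pair(agent, "valued", duration_s, seeds[[2 * i - 1]])
      d <- simulate_devaluation_pair(agent, "devalued", duration_s, seeds[[2 * i]])
      tibble(
        subject = i,
        valued = sum(v$event_type == "nose_poke_active"),
        devalued = sum(d$event_type == "nose_poke_active")
      )
    })
  })
}
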