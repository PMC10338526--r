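# End-to-end pipeline: simulate -> preprocess -> align -> decode -> stats.

#' Build a validated pipeline configuration
#'
#' Collects every stage's parameters with study-condition defaults: terminal
#' RR20 and RI120 sessions, an RR agent responding faster than the RI agent
#' (only the ordering is prescribed by the behavioural literature the
#' generator emulates), the default neural generator and dF/F parameters,
#' 2 s + 2 s peri-event windows, and the undersampled 4-fold SVM protocol.
#' `n_resamples` defaults to 50 here (not the protocol's canonical 400) to
#' keep a full pipeline run light; raise it for production runs.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_sessions Sessions simulated per condition.
#' @param session_cap_s,reward_cap Session caps for the simulated sessions.
#' @param rr_value,ri_value Terminal schedule parameters.
#' @param agent_rr,agent_ri [agent_params()] per condition.
#' @param neural A [neural_params()].
#' @param dff A [dff_params()].
#' @param pre_s,post_s Peri-event window (s).
#' @param decoding List with `k`, `n_resamples`, `input_range`, `cost`.
#' @param devaluation List with `n_subjects`, `goal_factor`, `habit_factor`,
#'   `duration_s`, `rate_hz`.
#' @param n_blocks Blocks for the trial-progression analysis.
#' @param threshold Calcium-event detection threshold (dF/F).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1,
                            n_sessions = 3,
                            session_cap_s = 600,
                            reward_cap = 60,
                            rr_value = 20,
                            ri_value = 120,
                            agent_rr = agent_params(nose_poke_rate_hz = 0.5),
                            agent_ri = agent_params(nose_poke_rate_hz = 0.25),
                            neural = neural_params(),
                            dff = dff_params(),
                            pre_s = 2,
                            post_s = 2,
                            decoding = list(),
                            devaluation = list(),
                            n_blocks = 10,
                            threshold = 0.02) {
  dec_def <- list(k = 4, n_resamples = 50, input_range = c(-2, 2), cost = 1)
  dev_def <- list(
    n_subjects = 8, goal_factor = 0.3, habit_factor = 1,
    duration_s = 600, rate_hz = 0.5
  )
  check_keys <- function(user, def, what) {
    extra <- setdiff(names(user), names(def))
    if (length(extra)) {
      stop("unknown ", what, " key(s): ", paste(extra, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(def, user)
  }
  decoding <- check_keys(decoding, dec_def, "decoding")
  devaluation <- check_keys(devaluation, dev_def, "devaluation")
  stopifnot(
    inherits(agent_rr, "agent_params"), inherits(agent_ri, "agent_params"),
    inherits(neural, "neural_params"), inherits(dff, "dff_params"),
    n_sessions >= 1, pre_s > 0, post_s > 0, n_blocks >= 2, threshold > 0
  )
  structure(
    list(
      seed = seed, n_sessions = n_sessions,
      session_cap_s = session_cap_s, reward_cap = reward_cap,
      rr_value = rr_value, ri_value = ri_value,
      agent_rr = agent_rr, agent_ri = agent_ri,
      neural = neural, dff = dff,
      pre_s = pre_s, post_s = post_s,
      decoding = decoding, devaluation = devaluation,
      n_blocks = n_blocks, threshold = threshold
    ),
    class = "pipeline_config"
  )
}

pipeline_condition <- function(cfg, condition, seeds) {
  kind <- if (condition == "RR") "RR" else "RI"
  value <- if (condition == "RR") cfg$rr_value else cfg$ri_value
  agent <- if (condition == "RR") cfg$agent_rr else cfg$agent_ri
  pems <- vector("list", cfg$n_sessions)
  ca <- vector("list", cfg$n_sessions)
  for (i in seq_len(cfg$n_sessions)) {
    s <- simulate_session(
      schedule_spec(kind, value, cfg$session_cap_s, cfg$reward_cap),
      agent,
      seed = seeds[2 * i - 1]
    )
    d <- compute_dff(generate_trace(s, cfg$neural, seed = seeds[2 * i]), cfg$dff)
    pems[[i]] <- extract_perievent(d, s, cfg$pre_s, cfg$post_s)
    ca[[i]] <- summarize_events(
      detect_events(d, cfg$threshold),
      attr(d, "duration_s")
    )
  }
  list(
    pem = bind_perievent(pems),
    ca_events = dplyr::bind_rows(ca, .id = "session")
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates terminal RR and RI sessions with coupled traces, computes dF/F,
#' aligns peri-event snippets, decodes condition per event class with the
#' undersampled SVM protocol, fits decile-block trends, runs goal- and
#' habit-agent devaluation cohorts, and summarises calcium events. All
#' randomness derives from `config$seed`, so identical configurations give
#' identical reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, per-stage tables are
#'   written as CSV/TSV and the report as `summary.json`.
#' @return A `pipeline_report` list: `decoding` (per-event-class metric
#'   means), `block_trends`, `devaluation`, `ca_events`, `config_seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  with_seed_(config$seed, {
    seeds <- derive_seeds(4 * config$n_sessions + 2)
    rr <- pipeline_condition(config, "RR", seeds[seq_len(2 * config$n_sessions)])
    ri <- pipeline_condition(
      config, "RI",
      seeds[(2 * config$n_sessions + 1):(4 * config$n_sessions)]
    )

    # Decode per event class wherever both conditions have enough trials.
    k <- config$decoding$k
    dec_rows <- list()
    results <- list()
    for (cl in EVENT_CLASSES) {
      n_rr <- sum(rr$pem$event_class == cl)
      n_ri <- sum(ri$pem$event_class == cl)
      if (min(n_rr, n_ri) < 2 * k) next
      ft <- build_features(rr$pem, ri$pem, cl, config$decoding$input_range)
      res <- run_svm_protocol(
        ft,
        k = k,
        n_resamples = config$decoding$n_resamples,
        cost = config$decoding$cost,
        seed = derive_seeds(1)
      )
      results[[cl]] <- res
      dec_rows[[cl]] <- dplyr::mutate(
        tidyr::pivot_wider(res$summary[, c("metric", "mean")],
          names_from = "metric", values_from = "mean"
        ),
        event_class = cl, n_rr = n_rr, n_ri = n_ri, .before = 1
      )
    }
    decoding <- dplyr::bind_rows(dec_rows)

    # Trial-progression block trends per condition and class.
    trend_rows <- list()
    for (cond in c("RR", "RI")) {
      pem <- if (cond == "RR") rr$pem else ri$pem
      for (cl in EVENT_CLASSES) {
        if (sum(pem$event_class == cl) < config$n_blocks) next
        bt <- blockwise_trend(pem, cl, config$n_blocks)
        trend_rows[[paste(cond, cl)]] <- tibble(
          condition = cond, event_class = cl,
          slope = bt$slope, intercept = bt$intercept, p_value = bt$p_value,
          n_events = bt$n_events
        )
      }
    }
    block_trends <- dplyr::bind_rows(trend_rows)

    # Devaluation cohorts: goal-directed vs habitual agents.
    dv <- config$devaluation
    goal <- devaluation_test(simulate_devaluation_cohort(
      dv$n_subjects,
      agent_params(
        nose_poke_rate_hz = dv$rate_hz,
        devaluation_factor = dv$goal_factor
      ),
      dv$duration_s,
      seed = seeds[4 * config$n_sessions + 1]
    ))
    habit <- devaluation_test(simulate_devaluation_cohort(
      dv$n_subjects,
      agent_params(
        nose_poke_rate_hz = dv$rate_hz,
        devaluation_factor = dv$habit_factor
      ),
      dv$duration_s,
      seed = seeds[4 * config$n_sessions + 2]
    ))
    devaluation <- tibble(
      agent = c("goal", "habit"),
      statistic = c(goal$statistic, habit$statistic),
      p_value = c(goal$p_value, habit$p_value),
      mean_index = c(goal$mean_index, habit$mean_index)
    )

    ca_events <- dplyr::bind_rows(
      dplyr::mutate(rr$ca_events, condition = "RR", .before = 1),
      dplyr::mutate(ri$ca_events, condition = "RI", .before = 1)
    )

    report <- structure(
      list(
        decoding = decoding,
        decoding_results = results,
        block_trends = block_trends,
        devaluation = devaluation,
        ca_events = ca_events,
        config_seed = config$seed
      ),
      class = "pipeline_report"
    )

    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      utils::write.csv(decoding, file.path(out_dir, "decoding.csv"), row.names = FALSE)
      utils::write.table(block_trends, file.path(out_dir, "block_trends.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      utils::write.table(devaluation, file.path(out_dir, "devaluation.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      utils::write.csv(ca_events, file.path(out_dir, "ca_events.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(
          seed = config$seed,
          mean_auc = stats::setNames(
            as.list(decoding$auc),
            decoding$event_class
          ),
          block_slopes = block_trends,
          devaluation_p = stats::setNames(
            as.list(devaluation$p_value),
            devaluation$agent
          )
        ),
        file.path(out_dir, "summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
    report
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n\nDecoding (mean over resamples):\n")
  print(x$decoding)
  cat("\nDevaluation tests:\n")
  print(x$devaluation)
  cat("\nBlock trends:\n")
  print(x$block_trends)
  invisible(x)
}
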