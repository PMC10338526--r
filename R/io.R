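# CSV/JSON I/O for event logs and fluorescence traces, plus deterministic
# test fixtures.

EVENT_LOG_HEADER <- c(
  "session_id", "time_s", "event_type", "rewarded",
  "schedule_kind", "schedule_value"
)

#' Write a behavioural event log as CSV
#'
#' Columns: `session_id`, `time_s`, `event_type`, `rewarded` (0/1),
#' `schedule_kind`, `schedule_value`.
#'
#' @param session An `operant_session`.
#' @param path Output CSV path.
#' @param session_id Identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(session, path, session_id = "S1") {
  sch <- attr(session, "schedule")
  df <- data.frame(
    session_id = rep(session_id, nrow(session)),
    time_s = session$time_s,
    event_type = session$event_type,
    rewarded = as.integer(session$rewarded),
    schedule_kind = rep(if (is.null(sch)) NA_character_ else sch$kind, nrow(session)),
    schedule_value = rep(if (is.null(sch)) NA_real_ else sch$value, nrow(session)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioural event log CSV
#'
#' Validates the header, event types, the 0/1 `rewarded` flag and time
#' monotonicity (non-monotone files are an error naming the offending line,
#' never silently sorted).
#'
#' @param path CSV path as written by [write_event_log()].
#' @return An `operant_session`. A header-only file yields an empty session
#'   with zero rewards.
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), EVENT_LOG_HEADER)) {
    stop("bad event-log header: expected ", paste(EVENT_LOG_HEADER, collapse = ","),
      call. = FALSE
    )
  }
  if (nrow(df) == 0) {
    return(new_operant_session(
      tibble(time_s = numeric(0), event_type = character(0), rewarded = logical(0)),
      schedule = NULL, agent = NULL, duration_s = 0, n_rewards = 0L,
      termination = NA_character_, condition_label = NA_character_
    ))
  }
  bad_type <- which(!df$event_type %in% EVENT_TYPES)
  if (length(bad_type)) {
    stop("unknown event_type at line ", bad_type[1] + 1L, ": ",
      df$event_type[bad_type[1]],
      call. = FALSE
    )
  }
  bad_rew <- which(!df$rewarded %in% c(0L, 1L))
  if (length(bad_rew)) {
    stop("`rewarded` must be 0/1 at line ", bad_rew[1] + 1L, call. = FALSE)
  }
  dec <- which(diff(df$time_s) < 0)
  if (length(dec)) {
    stop("non-monotone time_s at line ", dec[1] + 2L, call. = FALSE)
  }
  if (any(df$time_s < 0)) stop("negative time_s", call. = FALSE)
  kind <- df$schedule_kind[1]
  sch <- if (!is.na(kind) && kind %in% c("FR", "RR", "RI", "EXTINCTION")) {
    schedule_spec(kind, if (kind == "EXTINCTION") NULL else df$schedule_value[1])
  } else {
    NULL
  }
  cond <- if (is.null(sch)) NA_character_ else switch(sch$kind,
    RR = "RR", FR = "RR", RI = "RI", NA_character_
  )
  new_operant_session(
    tibble(
      time_s = df$time_s,
      event_type = df$event_type,
      rewarded = df$rewarded == 1L
    ),
    schedule = sch, agent = NULL,
    duration_s = max(df$time_s),
    n_rewards = sum(df$event_type == "reward_delivery"),
    termination = NA_character_,
    condition_label = cond
  )
}

#' Write a fluorescence trace as CSV plus a JSON sidecar
#'
#' The CSV holds `time_s`, `fluorescence`; the sidecar `<path>.json` records
#' the frame rate.
#'
#' @param trace A `raw_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time_s, fluorescence = trace$fluorescence),
    path,
    row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(fps = attr(trace, "fps"), condition_label = attr(trace, "condition_label")),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a fluorescence trace CSV with its JSON sidecar
#'
#' @param path CSV path as written by [write_trace()].
#' @return A `raw_trace`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("time_s", "fluorescence"))) {
    stop("bad trace header: expected time_s,fluorescence", call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar)
  cond <- meta$condition_label
  tibble::new_tibble(
    tibble(time_s = df$time_s, fluorescence = df$fluorescence),
    nrow = nrow(df),
    class = "raw_trace",
    fps = as.numeric(meta$fps),
    condition_label = if (is.null(cond)) NA_character_ else as.character(cond),
    duration_s = max(df$time_s)
  )
}

#' Write a small deterministic fixture set
#'
#' Generates two RR20 and two RI120 sessions (short time caps) with coupled
#' synthetic traces and writes them as event-log CSVs and trace CSVs with
#' sidecars. Identical seeds give identical files.
#'
#' @param outdir Writable output directory (created if absent).
#' @param seed Master seed.
#' @return A tibble of `session_id`, `event_log`, `trace` paths, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  }
  specs <- list(
    list(id = "rr1", kind = "RR", value = 20),
    list(id = "rr2", kind = "RR", value = 20),
    list(id = "ri1", kind = "RI", value = 120),
    list(id = "ri2", kind = "RI", value = 120)
  )
  out <- with_seed_(seed, {
    seeds <- matrix(derive_seeds(2 * length(specs)), ncol = 2)
    purrr::imap_dfr(specs, function(sp, i) {
      s <- simulate_session(
        schedule_spec(sp$kind, sp$value, session_cap_s = 120),
        agent_params(nose_poke_rate_hz = 0.5),
        seed = seeds[i, 1]
      )
      ep <- file.path(outdir, paste0("fixture_", sp$id, "_events.csv"))
      tp <- file.path(outdir, paste0("fixture_", sp$id, "_trace.csv"))
      write_event_log(s, ep, session_id = sp$id)
      write_trace(generate_trace(s, neural_params(), seed = seeds[i, 2]), tp)
      tibble(session_id = sp$id, event_log = ep, trace = tp)
    })
  })
  invisible(out)
}
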