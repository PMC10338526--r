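# Internal helpers shared across modules.

# Canonical behavioural event types and the six peri-event classes.
EVENT_TYPES <- c(
  "nose_poke_active", "nose_poke_inactive",
  "magazine_entry", "magazine_exit", "reward_delivery"
)

EVENT_CLASSES <- c(
  "NP R+", "NP R-",
  "M_entry R+", "M_entry R-",
  "M_exit R+", "M_exit R-"
)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed runs in the ambient stream.
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Draw n sub-stream seeds from the current RNG state (31-bit range).
derive_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

#' Map behavioural events to peri-event classes
#'
#' Active nose pokes, magazine entries and magazine exits map to the six
#' peri-event classes (`"NP R+"`, `"NP R-"`, `"M_entry R+"`, `"M_entry R-"`,
#' `"M_exit R+"`, `"M_exit R-"`); inactive pokes and reward deliveries map
#' to `NA` (they carry no peri-event class of their own).
#'
#' @param event_type Character vector of event types.
#' @param rewarded Logical vector, same length.
#' @return Character vector of class labels (or `NA`).
#' @export
event_class_of <- function(event_type, rewarded) {
  base <- c(
    nose_poke_active = "NP",
    magazine_entry = "M_entry",
    magazine_exit = "M_exit"
  )[event_type]
  out <- ifelse(is.na(base), NA_character_,
    paste0(base, ifelse(rewarded, " R+", " R-"))
  )
  unname(out)
}
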