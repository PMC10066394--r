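#' Vigilance states
#'
#' The three vigilance states scored from rodent polysomnography, in the
#' canonical order used throughout the package: wake, NREM sleep, REM sleep.
#' All hypnogram columns and classifier outputs are factors with these levels.
#'
#' @return Character vector `c("WAKE", "NREM", "REM")`.
#' @export
#' @examples
#' vigilance_states()
vigilance_states <- function() c("WAKE", "NREM", "REM")

#' Duration of one scoring epoch, in seconds
#'
#' Polysomnography is scored on a fixed 10-s epoch grid; every hypnogram,
#' feature table and simulation in this package shares it.
#'
#' @return The number 10.
#' @export
epoch_seconds <- function() 10

# Coerce a state input (character/factor, any case) to the canonical factor.
as_state_factor <- function(x, arg = "state") {
  if (is.factor(x)) x <- as.character(x)
  if (!is.character(x)) {
    abort_validation(sprintf("`%s` must be character or factor.", arg))
  }
  up <- toupper(x)
  bad <- !(up %in% vigilance_states()) & !is.na(up)
  if (any(bad)) {
    abort_validation(sprintf(
      "`%s` contains labels other than WAKE/NREM/REM: %s",
      arg, paste(unique(x[bad])[seq_len(min(3, length(unique(x[bad]))))], collapse = ", ")
    ))
  }
  factor(up, levels = vigilance_states())
}

# Classed condition so callers/tests can distinguish input validation failures.
abort_validation <- function(message, ...) {
  rlang::abort(message, class = "somnoscore_validation_error", ...)
}

# Extract the state vector from a hypnogram tibble (or bare vector).
hypnogram_states <- function(hypnogram) {
  if (is.data.frame(hypnogram)) {
    if (!"state" %in% names(hypnogram)) {
      abort_validation("A hypnogram data frame must have a `state` column.")
    }
    x <- hypnogram$state
  } else {
    x <- hypnogram
  }
  if (length(x) == 0) abort_validation("Hypnogram is empty.")
  as_state_factor(x)
}

# Starting zeitgeber time (h) of a hypnogram tibble; defaults to 0.
hypnogram_start_zt <- function(hypnogram) {
  if (is.data.frame(hypnogram) && "zt" %in% names(hypnogram) && nrow(hypnogram) > 0) {
    hypnogram$zt[1]
  } else {
    0
  }
}
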