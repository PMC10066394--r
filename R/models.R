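#' Markov state-transition model for vigilance-state simulation
#'
#' A first-order Markov chain on the 10-s epoch grid, with separate
#' row-stochastic 3x3 transition matrices for the light and dark phases
#' (rows/columns ordered WAKE, NREM, REM; entry \[i, j\] is the per-epoch
#' probability of moving from state i to state j).
#'
#' The defaults are free parameters of the simulator, not measured values:
#' they were chosen so the stationary occupancies approximate typical rat
#' polysomnography (light phase roughly 55% NREM / 10% REM / 35% wake; dark
#' phase roughly 30% / 5% / 65%), per-state mean dwell times are on the
#' minutes scale (geometric mean dwell `1/(1 - p_stay)` epochs), and REM is
#' entered only from NREM (`WAKE -> REM = 0`), as in rodent physiology.
#' All of this is overridable.
#'
#' @param light_matrix,dark_matrix 3x3 row-stochastic matrices (rows sum to 1
#'   within 1e-12, entries nonnegative).
#' @param initial_state State the chain starts in. Default `"WAKE"`.
#'
#' @return An object of class `state_transition_model`.
#' @export
#' @examples
#' m <- state_transition_model()
#' rowSums(m$light_matrix)
state_transition_model <- function(light_matrix = default_light_matrix(),
                                   dark_matrix = default_dark_matrix(),
                                   initial_state = "WAKE") {
  validate_stochastic_matrix(light_matrix, "light_matrix")
  validate_stochastic_matrix(dark_matrix, "dark_matrix")
  structure(
    list(
      light_matrix = light_matrix,
      dark_matrix = dark_matrix,
      initial_state = as.character(as_state_factor(initial_state, "initial_state"))
    ),
    class = "state_transition_model"
  )
}

#' @rdname state_transition_model
#' @export
default_light_matrix <- function() {
  m <- matrix(c(
    0.920, 0.080, 0.000,
    0.030, 0.945, 0.025,
    0.115, 0.020, 0.865
  ), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(vigilance_states(), vigilance_states())
  m
}

#' @rdname state_transition_model
#' @export
default_dark_matrix <- function() {
  m <- matrix(c(
    0.958, 0.042, 0.000,
    0.070, 0.905, 0.025,
    0.160, 0.020, 0.820
  ), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(vigilance_states(), vigilance_states())
  m
}

validate_stochastic_matrix <- function(m, arg) {
  if (!is.matrix(m) || !is.numeric(m) || any(dim(m) != c(3, 3))) {
    abort_validation(sprintf("`%s` must be a numeric 3x3 matrix.", arg))
  }
  if (any(m < 0)) {
    abort_validation(sprintf("`%s` has negative entries.", arg))
  }
  if (any(abs(rowSums(m) - 1) > 1e-12)) {
    abort_validation(sprintf("`%s` rows must each sum to 1 (within 1e-12).", arg))
  }
  invisible(m)
}

#' State-dependent signal model for synthetic telemetry
#'
#' Describes how each vigilance state expresses itself in the recorded
#' channels: the relative EEG power split over the five classical bands
#' (delta, theta, alpha, sigma, beta), EEG and EMG root-mean-square
#' amplitudes in microvolts, the Poisson rate of cage-activity counts per
#' 10-s epoch by phase (activity occurs only in WAKE epochs), and a cosinor
#' (mesor + amplitude + acrophase) for core body temperature.
#'
#' Defaults encode the standard phenomenology: wake is low-amplitude,
#' high-frequency EEG with high EMG tone; NREM is high-amplitude,
#' delta-dominant EEG with low EMG; REM is low-amplitude, theta-dominant EEG
#' with near-atonic EMG. Amplitude numbers are simulator free parameters.
#'
#' @param band_weights 3x5 matrix (rows WAKE/NREM/REM, columns
#'   delta/theta/alpha/sigma/beta) of nonnegative relative power fractions;
#'   each row must sum to 1.
#' @param eeg_amplitude,emg_amplitude Named per-state RMS amplitudes, uV.
#'   EMG must satisfy REM < NREM < WAKE.
#' @param activity_rate_by_phase Named vector `c(light = , dark = )`, mean
#'   activity counts per WAKE epoch.
#' @param temperature_mesor,temperature_amplitude,temperature_acrophase
#'   Cosinor parameters for core temperature: mean (deg C), half peak-to-trough
#'   amplitude (deg C) and peak time (ZT hours).
#' @param temperature_noise_sd Gaussian jitter on per-epoch temperature, deg C.
#'
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(band_weights = default_band_weights(),
                         eeg_amplitude = c(WAKE = 40, NREM = 120, REM = 50),
                         emg_amplitude = c(WAKE = 80, NREM = 30, REM = 8),
                         activity_rate_by_phase = c(light = 2, dark = 6),
                         temperature_mesor = 37.3,
                         temperature_amplitude = 0.5,
                         temperature_acrophase = 18,
                         temperature_noise_sd = 0.1) {
  if (!is.matrix(band_weights) || any(dim(band_weights) != c(3, 5))) {
    abort_validation("`band_weights` must be a 3x5 matrix (states x bands).")
  }
  if (any(band_weights < 0) || any(abs(rowSums(band_weights) - 1) > 1e-9)) {
    abort_validation("`band_weights` rows must be nonnegative and sum to 1.")
  }
  for (nm in c("eeg_amplitude", "emg_amplitude")) {
    v <- get(nm)
    if (!all(vigilance_states() %in% names(v)) || any(v[vigilance_states()] <= 0)) {
      abort_validation(sprintf("`%s` must be positive and named WAKE/NREM/REM.", nm))
    }
  }
  if (!(emg_amplitude[["REM"]] < emg_amplitude[["NREM"]] &&
        emg_amplitude[["NREM"]] < emg_amplitude[["WAKE"]])) {
    abort_validation("EMG amplitudes must be ordered REM < NREM < WAKE (atonia in REM).")
  }
  if (!all(c("light", "dark") %in% names(activity_rate_by_phase)) ||
      any(activity_rate_by_phase < 0)) {
    abort_validation("`activity_rate_by_phase` must be nonnegative, named light/dark.")
  }
  structure(
    list(
      band_weights = band_weights,
      eeg_amplitude = eeg_amplitude[vigilance_states()],
      emg_amplitude = emg_amplitude[vigilance_states()],
      activity_rate_by_phase = activity_rate_by_phase[c("light", "dark")],
      temperature_mesor = temperature_mesor,
      temperature_amplitude = temperature_amplitude,
      temperature_acrophase = temperature_acrophase,
      temperature_noise_sd = temperature_noise_sd
    ),
    class = "signal_model"
  )
}

#' @rdname signal_model
#' @export
default_band_weights <- function() {
  w <- matrix(c(
    # delta theta alpha sigma  beta
    0.15, 0.25, 0.25, 0.18, 0.17, # WAKE: broadband, high-frequency tilt
    0.55, 0.20, 0.12, 0.08, 0.05, # NREM: delta-dominant
    0.12, 0.50, 0.18, 0.10, 0.10  # REM: theta-dominant
  ), nrow = 3, byrow = TRUE)
  dimnames(w) <- list(vigilance_states(), band_names())
  w
}

#' Treatment effect applied inside a zeitgeber-time window
#'
#' Directional knobs emulating an acute hypnotic/sedative drug effect: a
#' multiplier (> 1 promotes sleep) on the wake-to-sleep transition
#' probabilities, a multiplier on the NREM-relevant delta band weight, a
#' multiplier on the cage-activity rate, and an additive core-temperature
#' offset. Effects apply only to epochs whose ZT falls in
#' \[`window[1]`, `window[2]`) hours; modified transition rows are
#' renormalized to sum to 1.
#'
#' @param sleep_propensity_multiplier Nonnegative multiplier on the
#'   WAKE->NREM and WAKE->REM transition probabilities.
#' @param delta_power_multiplier Positive multiplier on the delta band weight
#'   (row renormalized), deepening NREM EEG.
#' @param activity_multiplier Positive multiplier on the activity Poisson rate.
#' @param temperature_offset Additive offset, deg C (negative = hypothermia).
#' @param window Length-2 ZT window (hours), half-open.
#'
#' @return An object of class `treatment_effect`.
#' @export
#' @examples
#' treatment_effect(sleep_propensity_multiplier = 1.6)
treatment_effect <- function(sleep_propensity_multiplier = 1.6,
                             delta_power_multiplier = 1.3,
                             activity_multiplier = 0.7,
                             temperature_offset = -0.4,
                             window = c(0, 12)) {
  if (sleep_propensity_multiplier < 0) {
    abort_validation("`sleep_propensity_multiplier` must be >= 0.")
  }
  if (delta_power_multiplier <= 0 || activity_multiplier <= 0) {
    abort_validation("Power/activity multipliers must be > 0.")
  }
  if (length(window) != 2 || window[2] <= window[1]) {
    abort_validation("`window` must be an increasing length-2 ZT interval.")
  }
  structure(
    list(
      sleep_propensity_multiplier = sleep_propensity_multiplier,
      delta_power_multiplier = delta_power_multiplier,
      activity_multiplier = activity_multiplier,
      temperature_offset = temperature_offset,
      window = as.numeric(window)
    ),
    class = "treatment_effect"
  )
}

# Apply the sleep-propensity multiplier to the WAKE row and renormalize.
apply_treatment_to_matrix <- function(m, treatment) {
  out <- m
  w <- out["WAKE", ]
  w[c("NREM", "REM")] <- w[c("NREM", "REM")] * treatment$sleep_propensity_multiplier
  s <- sum(w)
  if (s <= 0) abort_validation("Treatment zeroed the entire WAKE transition row.")
  out["WAKE", ] <- w / s
  out
}

# TRUE for epochs whose ZT lies in the treatment window (half-open).
in_effect_window <- function(zt, treatment) {
  if (is.null(treatment)) return(rep(FALSE, length(zt)))
  zt >= treatment$window[1] & zt < treatment$window[2]
}
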