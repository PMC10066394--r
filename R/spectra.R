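#' State- and phase-resolved EEG power spectrum
#'
#' Averages the 40 normalized 0.5-Hz channel powers over all epochs carrying
#' the given vigilance state within the given phase, yielding the mean
#' power-fraction spectrum on the 0-20 Hz grid. Epochs are selected by the
#' hypnogram under analysis (truth labels for simulations, predicted labels
#' for end-to-end runs). Spectra are fractions of each epoch's total 0-20 Hz
#' power; because the DC bin is excluded from channel 0, total spectral mass
#' is at most 1.
#'
#' @param features Per-epoch feature tibble from [featurize_recording()].
#' @param hypnogram Hypnogram tibble aligned 1:1 with `features` (may be the
#'   `state` column already present in `features`, in which case pass
#'   `hypnogram = NULL`).
#' @param state Vigilance state to select.
#' @param phase `"light"` or `"dark"`.
#' @param schedule A [light_dark_schedule()].
#'
#' @return A `spectral_profile` tibble: `state`, `phase`, `bin_hz` (channel
#'   centers 0.25, 0.75, ..., 19.75), `power_fraction`, `n_epochs`.
#' @export
state_phase_spectrum <- function(features, hypnogram = NULL,
                                 state = "NREM", phase = c("light", "dark"),
                                 schedule = light_dark_schedule()) {
  phase <- match.arg(phase)
  state <- as.character(as_state_factor(state))
  labels <- if (is.null(hypnogram)) {
    if (!"state" %in% names(features)) {
      abort_validation("Supply a hypnogram or features with a `state` column.")
    }
    as_state_factor(features$state)
  } else {
    st <- hypnogram_states(hypnogram)
    if (length(st) != nrow(features)) {
      abort_validation(sprintf(
        "Hypnogram (%d labels) and features (%d epochs) are not aligned.",
        length(st), nrow(features)
      ))
    }
    st
  }
  ep_phase <- phase_of_zt(features$zt, schedule)
  keep <- labels == state & ep_phase == phase
  if (!any(keep)) {
    abort_validation(sprintf("No %s epochs in the %s phase.", state, phase))
  }
  ch_cols <- sprintf("ch%02d", 0:39)
  m <- as.matrix(features[keep, ch_cols])
  tibble::tibble(
    state = factor(state, levels = vigilance_states()),
    phase = factor(phase, levels = c("light", "dark")),
    bin_hz = 0:39 * 0.5 + 0.25,
    power_fraction = unname(colMeans(m)),
    n_epochs = sum(keep)
  )
}

#' Band power from a spectral profile
#'
#' Sums the power fractions of all 0.5-Hz bins whose center frequency falls
#' in the band's half-open interval \[lo, hi).
#'
#' @param profile Tibble from [state_phase_spectrum()] (columns `bin_hz`,
#'   `power_fraction`).
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`, `"sigma"`,
#'   `"beta"`) or a numeric `c(lo, hi)` within \[0, 20).
#'
#' @return Power fraction (single number).
#' @export
#' @examples
#' # a flat white-noise spectrum puts 4/20 of its mass in theta (4-8 Hz)
band_power <- function(profile, band = "delta") {
  if (is.character(band)) {
    defs <- band_definitions()
    if (!band %in% defs$band) {
      abort_validation(sprintf("Unknown band '%s'.", band))
    }
    lim <- unlist(defs[defs$band == band, c("lo_hz", "hi_hz")])
  } else {
    lim <- as.numeric(band)
  }
  if (length(lim) != 2 || lim[1] < 0 || lim[2] > 20 || lim[2] <= lim[1]) {
    abort_validation("Band limits must be an increasing interval within [0, 20).")
  }
  sum(profile$power_fraction[profile$bin_hz >= lim[1] & profile$bin_hz < lim[2]])
}

#' Per-bin spectral contrast between treatments
#'
#' Treated minus vehicle power fraction, per frequency bin, for two spectral
#' profiles on the same state/phase/bin grid. Anti-symmetric under argument
#' swap.
#'
#' @param treated,vehicle Tibbles from [state_phase_spectrum()].
#'
#' @return Tibble `state`, `phase`, `bin_hz`, `vehicle`, `treated`,
#'   `difference`.
#' @export
spectral_contrast <- function(treated, vehicle) {
  if (!identical(treated$bin_hz, vehicle$bin_hz) ||
      !identical(as.character(treated$state), as.character(vehicle$state)) ||
      !identical(as.character(treated$phase), as.character(vehicle$phase))) {
    abort_validation("Profiles differ in state, phase or frequency grid.")
  }
  p_veh <- vehicle$power_fraction
  p_trt <- treated$power_fraction
  tibble::tibble(
    state = treated$state,
    phase = treated$phase,
    bin_hz = treated$bin_hz,
    vehicle = p_veh,
    treated = p_trt,
    difference = p_trt - p_veh
  )
}

#' Band powers straight from a raw signal epoch
#'
#' Channelizes one 10-s epoch with the same DFT path the featurizer uses
#' and returns the five classical band powers as fractions of total 0-20 Hz
#' power. Exists so band powers computed from [state_phase_spectrum()]
#' output can be cross-checked against the raw-signal route.
#'
#' @param x Numeric vector of one epoch of EEG samples.
#' @param sampling_rate Sampling rate, Hz.
#'
#' @return Named numeric vector of the five band-power fractions.
#' @export
epoch_band_powers <- function(x, sampling_rate) {
  ch <- epoch_channel_power(x, sampling_rate)
  total <- sum(ch)
  if (total <= 0) return(stats::setNames(rep(0, 5), band_names()))
  frac <- ch / total
  centers <- 0:39 * 0.5 + 0.25
  defs <- band_definitions()
  out <- vapply(seq_len(5), function(b) {
    sum(frac[centers >= defs$lo_hz[b] & centers < defs$hi_hz[b]])
  }, numeric(1))
  stats::setNames(out, band_names())
}
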