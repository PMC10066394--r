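#' Simulate a vigilance-state sequence (hypnogram)
#'
#' Draws a first-order Markov chain on the 10-s epoch grid. Each epoch's
#' transition row comes from the light or dark matrix according to the
#' epoch's zeitgeber time; epochs inside the treatment effect window use the
#' treatment-modified matrix (wake-to-sleep probabilities scaled and the row
#' renormalized).
#'
#' @param model A [state_transition_model()].
#' @param schedule A [light_dark_schedule()].
#' @param duration_h Recording length in hours; must be a positive multiple
#'   of one 10-s epoch.
#' @param treatment Optional [treatment_effect()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @param start_zt Zeitgeber time (hours) of the first epoch. Default 0.
#'
#' @return A hypnogram tibble with columns `epoch` (0-based), `zt` (hours)
#'   and `state` (factor WAKE/NREM/REM).
#' @export
#' @examples
#' h <- simulate_hypnogram(duration_h = 1, seed = 1)
#' table(h$state)
simulate_hypnogram <- function(model = state_transition_model(),
                               schedule = light_dark_schedule(),
                               duration_h = 24,
                               treatment = NULL,
                               seed = 1,
                               start_zt = 0) {
  stopifnot(inherits(model, "state_transition_model"))
  n_epochs <- duration_h * 3600 / epoch_seconds()
  if (duration_h <= 0 || abs(n_epochs - round(n_epochs)) > 1e-9) {
    abort_validation("`duration_h` must be a positive multiple of one 10-s epoch.")
  }
  n_epochs <- as.integer(round(n_epochs))
  epoch <- seq_len(n_epochs) - 1L
  zt <- zt_of_epoch(epoch, start_zt, schedule$period)
  phase <- phase_of_zt(zt, schedule)
  treated <- in_effect_window(zt, treatment)

  # Four possible per-epoch transition matrices, indexed once up front.
  mats <- list(
    light = model$light_matrix,
    dark = model$dark_matrix,
    light_rx = if (is.null(treatment)) NULL else
      apply_treatment_to_matrix(model$light_matrix, treatment),
    dark_rx = if (is.null(treatment)) NULL else
      apply_treatment_to_matrix(model$dark_matrix, treatment)
  )
  mat_key <- paste0(as.character(phase), ifelse(treated, "_rx", ""))

  states <- integer(n_epochs)
  withr::with_seed(seed, {
    u <- stats::runif(n_epochs)
    cur <- match(model$initial_state, vigilance_states())
    # Cumulative rows cached per matrix key for the inner loop.
    cum <- lapply(mats[unique(mat_key)], function(m) t(apply(m, 1, cumsum)))
    for (i in seq_len(n_epochs)) {
      states[i] <- cur
      if (i < n_epochs) {
        cr <- cum[[mat_key[i + 1L]]][cur, ]
        cur <- findInterval(u[i + 1L], cr, left.open = TRUE) + 1L
        if (cur > 3L) cur <- 3L
      }
    }
  })

  tibble::tibble(
    epoch = epoch,
    zt = zt,
    state = factor(vigilance_states()[states], levels = vigilance_states())
  )
}

# Band names and their half-open frequency limits (Hz). delta starts at
# 0.5 Hz; the five bands tile (0.5, 20).
band_names <- function() c("delta", "theta", "alpha", "sigma", "beta")

#' Classical EEG frequency bands
#'
#' Half-open bands tiling 0.5-20 Hz: delta (0.5-4), theta (4-8), alpha
#' (8-12), sigma (12-16), beta (16-20).
#'
#' @return Tibble with columns `band`, `lo_hz`, `hi_hz`.
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = band_names(),
    lo_hz = c(0.5, 4, 8, 12, 16),
    hi_hz = c(4, 8, 12, 16, 20)
  )
}

#' Synthesize telemetry signals for a hypnogram
#'
#' Generates, per 10-s epoch, EEG as band-limited Gaussian noise: for each of
#' the five classical bands, white noise is passed through an ideal (FFT
#' brick-wall) band filter and the components are weighted by the epoch
#' state's band-weight fractions, then the epoch is scaled to the state's
#' RMS amplitude. EMG is white Gaussian noise scaled to the state's RMS
#' amplitude; cage activity is a per-epoch Poisson count in WAKE epochs only;
#' core temperature follows a cosinor plus Gaussian jitter. A treatment
#' multiplies the delta band weight (row renormalized through the amplitude
#' scaling), scales the activity rate and offsets temperature, for epochs
#' inside its effect window.
#'
#' @param hypnogram Hypnogram tibble (from [simulate_hypnogram()] or read
#'   from disk) giving one state per 10-s epoch.
#' @param model A [signal_model()].
#' @param schedule A [light_dark_schedule()].
#' @param sampling_rate Sampling rate in Hz, at least 40 (Nyquist for the
#'   20 Hz analysis ceiling); `10 * sampling_rate` must be an integer.
#'   Default 250.
#' @param treatment Optional [treatment_effect()].
#' @param seed Integer seed. Channel sub-streams are derived from it
#'   deterministically, so identical inputs give bit-identical signals.
#' @param subject_id,treatment_label,prenatal_label Metadata carried on the
#'   recording (subject name; vehicle/drug; control/insult).
#'
#' @return A `recording` object: list with numeric `eeg` and `emg` (uV),
#'   `sampling_rate`, `start_zt`, an `epochs` tibble (`epoch`, `zt`,
#'   `activity`, `temperature_c`) and metadata fields (`subject_id`,
#'   `treatment_label`, `prenatal_label`).
#' @export
synthesize_signals <- function(hypnogram,
                               model = signal_model(),
                               schedule = light_dark_schedule(),
                               sampling_rate = 250,
                               treatment = NULL,
                               seed = 1,
                               subject_id = "sim",
                               treatment_label = if (is.null(treatment)) "vehicle" else "drug",
                               prenatal_label = "control") {
  stopifnot(inherits(model, "signal_model"))
  if (sampling_rate < 40) {
    abort_validation("`sampling_rate` must be >= 40 Hz (Nyquist for 20 Hz analysis).")
  }
  n <- 10 * sampling_rate
  if (abs(n - round(n)) > 1e-9) {
    abort_validation("10 * sampling_rate must be an integer number of samples.")
  }
  n <- as.integer(round(n))
  state <- hypnogram_states(hypnogram)
  n_ep <- length(state)
  zt <- if (is.data.frame(hypnogram) && "zt" %in% names(hypnogram)) {
    hypnogram$zt
  } else {
    zt_of_epoch(seq_len(n_ep) - 1L, 0, schedule$period)
  }
  treated <- in_effect_window(zt, treatment)

  # Per-epoch band-weight pattern: one of up to 6 (3 states x treated yes/no).
  weights <- model$band_weights
  weights_rx <- weights
  if (!is.null(treatment)) {
    weights_rx[, "delta"] <- weights_rx[, "delta"] * treatment$delta_power_multiplier
    weights_rx <- weights_rx / rowSums(weights_rx)
  }
  pattern <- as.integer(state) + 3L * treated # 1..3 plain, 4..6 treated
  pat_weights <- rbind(weights, weights_rx)   # 6 x 5

  seeds <- derive_subseeds(seed, 4)
  eeg <- synth_eeg(pattern, pat_weights, model$eeg_amplitude[as.integer(state)],
                   n, sampling_rate, seeds[1])
  emg <- synth_scaled_noise(model$emg_amplitude[as.integer(state)], n, seeds[2])

  phase <- phase_of_zt(zt, schedule)
  rate <- unname(model$activity_rate_by_phase[as.character(phase)])
  if (!is.null(treatment)) rate[treated] <- rate[treated] * treatment$activity_multiplier
  withr::with_seed(seeds[3], {
    activity <- ifelse(state == "WAKE", stats::rpois(n_ep, rate), 0L)
  })
  withr::with_seed(seeds[4], {
    temperature <- model$temperature_mesor +
      model$temperature_amplitude *
        cos(2 * pi * (zt - model$temperature_acrophase) / schedule$period) +
      stats::rnorm(n_ep, sd = model$temperature_noise_sd)
  })
  if (!is.null(treatment)) {
    temperature[treated] <- temperature[treated] + treatment$temperature_offset
  }

  new_recording(
    eeg = eeg, emg = emg, sampling_rate = sampling_rate,
    start_zt = zt[1],
    epochs = tibble::tibble(
      epoch = seq_len(n_ep) - 1L, zt = zt,
      activity = as.integer(activity), temperature_c = temperature
    ),
    subject_id = subject_id, treatment_label = treatment_label,
    prenatal_label = prenatal_label
  )
}

# EEG synthesis: complex-Gaussian spectral coefficients confined to the five
# bands (ideal band filtering of white noise), Hermitian-completed and
# inverse-FFT'd in chunks, then scaled to each epoch's target RMS.
synth_eeg <- function(pattern, pat_weights, amplitude, n, sampling_rate, seed) {
  nb <- n %/% 2L
  freq <- (seq_len(nb - 1L)) / 10 # positive-frequency bins, Hz (0.1-Hz grid)
  defs <- band_definitions()
  bin_band <- rep(NA_integer_, nb - 1L)
  for (b in seq_len(nrow(defs))) {
    bin_band[freq >= defs$lo_hz[b] & freq < defs$hi_hz[b]] <- b
  }
  active <- which(!is.na(bin_band))
  n_active <- length(active)
  bins_per_band <- tabulate(bin_band[active], nbins = 5)
  # Per-pattern standard deviation over active bins: variance w_b / m_b.
  sd_pat <- sqrt(t(pat_weights)[bin_band[active], , drop = FALSE] /
                   bins_per_band[bin_band[active]])

  n_ep <- length(pattern)
  out <- numeric(n_ep * n)
  chunk <- 1000L
  withr::with_seed(seed, {
    for (lo in seq(1L, n_ep, by = chunk)) {
      hi <- min(lo + chunk - 1L, n_ep)
      m <- hi - lo + 1L
      z <- matrix(complex(
        real = stats::rnorm(n_active * m), imaginary = stats::rnorm(n_active * m)
      ), nrow = n_active) * sd_pat[, pattern[lo:hi], drop = FALSE]
      spec <- matrix(0 + 0i, nrow = n, ncol = m)
      spec[active + 1L, ] <- z
      spec[n + 1L - active, ] <- Conj(z)
      x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
      rms <- sqrt(colMeans(x^2))
      rms[rms == 0] <- 1
      x <- sweep(x, 2, amplitude[lo:hi] / rms, `*`)
      out[(lo - 1L) * n + seq_len(m * n)] <- x
    }
  })
  out
}

# White Gaussian noise in epoch blocks, each scaled to an exact target RMS.
synth_scaled_noise <- function(amplitude, n, seed) {
  n_ep <- length(amplitude)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_ep * n), nrow = n)
  })
  rms <- sqrt(colMeans(x^2))
  as.vector(sweep(x, 2, amplitude / rms, `*`))
}

# Deterministic 32-bit sub-seeds for independent channel streams.
derive_subseeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, k))
}

#' Simulate a complete labeled recording
#'
#' Convenience wrapper: draws a hypnogram with [simulate_hypnogram()] and
#' synthesizes matching telemetry with [synthesize_signals()]. The same
#' `seed` drives both (through derived sub-streams), so a
#' (parameters, seed) pair is bit-reproducible.
#'
#' @inheritParams simulate_hypnogram
#' @inheritParams synthesize_signals
#' @param transition_model A [state_transition_model()].
#' @param signal_model A [signal_model()].
#'
#' @return A `simulated_recording`: list with `recording`, `hypnogram`
#'   (truth labels, one per epoch) and `seed`.
#' @export
#' @examples
#' sim <- simulate_recording(duration_h = 0.5, seed = 3)
#' nrow(sim$hypnogram)
simulate_recording <- function(duration_h = 24,
                               seed = 1,
                               transition_model = state_transition_model(),
                               signal_model = somnoscore::signal_model(),
                               schedule = light_dark_schedule(),
                               sampling_rate = 250,
                               treatment = NULL,
                               start_zt = 0,
                               subject_id = "sim",
                               treatment_label = if (is.null(treatment)) "vehicle" else "drug",
                               prenatal_label = "control") {
  seeds <- derive_subseeds(seed, 2)
  hyp <- simulate_hypnogram(transition_model, schedule, duration_h,
                            treatment = treatment, seed = seeds[1],
                            start_zt = start_zt)
  rec <- synthesize_signals(hyp, signal_model, schedule, sampling_rate,
                            treatment = treatment, seed = seeds[2],
                            subject_id = subject_id,
                            treatment_label = treatment_label,
                            prenatal_label = prenatal_label)
  structure(list(recording = rec, hypnogram = hyp, seed = seed),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cat(sprintf(
    "<simulated_recording> %d epochs (%.2f h), seed %d\n",
    nrow(x$hypnogram), nrow(x$hypnogram) * epoch_seconds() / 3600, x$seed
  ))
  print(x$recording)
  invisible(x)
}
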