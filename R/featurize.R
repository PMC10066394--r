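#' Segment a recording into 10-s epochs
#'
#' Tiles the recording with consecutive non-overlapping 10-s epochs anchored
#' at the recording start; a trailing partial epoch is discarded (with a
#' message). Each epoch carries its zeitgeber time.
#'
#' @param recording A `recording` object.
#'
#' @return Tibble with columns `epoch` (0-based), `start_s` (seconds from
#'   recording start) and `zt` (hours).
#' @export
segment_epochs <- function(recording) {
  stopifnot(inherits(recording, "recording"))
  dur <- recording_duration_s(recording)
  if (dur < epoch_seconds()) {
    abort_validation("Recording is shorter than one 10-s epoch.")
  }
  n_ep <- floor(dur / epoch_seconds())
  dropped <- dur - n_ep * epoch_seconds()
  if (dropped > 1e-9) {
    message(sprintf("Dropping trailing %.3f s (partial epoch).", dropped))
  }
  idx <- seq_len(n_ep) - 1L
  tibble::tibble(
    epoch = idx,
    start_s = idx * epoch_seconds(),
    zt = zt_of_epoch(idx, recording$start_zt)
  )
}

# Raw per-epoch spectral channelization shared by featurization and any
# direct band-power computation: single DFT of the rectangular-windowed
# 10-s epoch, periodogram power summed into 40 half-open 0.5-Hz channels
# covering [0, 20) Hz. The DC bin is excluded from channel 0 so a constant
# offset cannot dominate. Returns the un-normalized channel powers.
epoch_channel_power <- function(x, sampling_rate) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  nb <- n %/% 2L
  k <- seq_len(nb - 1L)                    # positive frequencies, DC excluded
  freq <- k * sampling_rate / n
  keep <- freq < 20
  ch <- floor(freq[keep] / 0.5 + 1e-9)     # half-open [c*0.5, (c+1)*0.5)
  as.vector(tapply(p[k[keep] + 1L], factor(ch, levels = 0:39), sum,
                   default = 0))
}

#' Compute per-epoch features from a recording
#'
#' Implements the 42-feature epoch representation: each 10-s epoch's EEG is
#' transformed to the frequency domain with a single DFT (rectangular
#' window, no detrending) and its power summed into 40 channels of equal
#' 0.5-Hz width spanning 0-20 Hz, each expressed as a fraction of the total
#' 0-20 Hz power (total power is the normalizer, not a separate feature);
#' the average EMG (epoch RMS, uV) and the relative cage-activity count
#' complete the vector. An epoch of exactly zero EEG power yields an
#' all-zero channel vector with a warning.
#'
#' @param recording A `recording` object.
#' @param hypnogram Optional hypnogram tibble; when supplied (and aligned
#'   1:1 with the epochs), a `state` column is attached for training.
#'
#' @return Tibble with one row per epoch: `epoch`, `zt`, `ch00`...`ch39`
#'   (power fractions), `avg_emg`, `activity`, and `state` when labels were
#'   given.
#' @export
#' @examples
#' sim <- simulate_recording(duration_h = 0.25, seed = 1)
#' f <- featurize_recording(sim$recording, sim$hypnogram)
#' ncol(dplyr::select(f, dplyr::starts_with("ch"))) # 40 spectral channels
featurize_recording <- function(recording, hypnogram = NULL) {
  stopifnot(inherits(recording, "recording"))
  eps <- segment_epochs(recording)
  n <- as.integer(epoch_seconds() * recording$sampling_rate)
  n_ep <- nrow(eps)

  if (anyNA(recording$eeg[seq_len(n_ep * n)]) ||
      anyNA(recording$emg[seq_len(n_ep * n)])) {
    bad <- which(vapply(seq_len(n_ep), function(i) {
      idx <- (i - 1L) * n + seq_len(n)
      anyNA(recording$eeg[idx]) || anyNA(recording$emg[idx])
    }, logical(1)))
    abort_validation(sprintf(
      "NaN/NA samples in epoch(s): %s",
      paste(utils::head(bad - 1L, 5), collapse = ", ")
    ))
  }

  eeg <- matrix(recording$eeg[seq_len(n_ep * n)], nrow = n)
  emg <- matrix(recording$emg[seq_len(n_ep * n)], nrow = n)

  ch <- channelize_epoch_matrix(eeg, recording$sampling_rate)
  totals <- colSums(ch)
  zero <- totals <= 0
  if (any(zero)) {
    warning(sprintf("%d epoch(s) with zero total EEG power; channel vector set to 0.",
                    sum(zero)))
    totals[zero] <- 1
  }
  frac <- t(sweep(ch, 2, totals, `/`))
  colnames(frac) <- sprintf("ch%02d", 0:39)

  out <- dplyr::bind_cols(
    eps[, c("epoch", "zt")],
    tibble::as_tibble(frac),
    tibble::tibble(
      avg_emg = sqrt(colMeans(emg^2)),
      activity = recording$epochs$activity[seq_len(n_ep)]
    )
  )
  if (!is.null(hypnogram)) {
    st <- hypnogram_states(hypnogram)
    if (length(st) != n_ep) {
      abort_validation(sprintf(
        "Hypnogram has %d labels but the recording has %d epochs.",
        length(st), n_ep
      ))
    }
    out$state <- st
  }
  out
}

# Vectorized channelization of an n_samples x n_epochs matrix: one DFT per
# column (chunked to bound memory), power summed into the 40 channels with
# rowsum. Returns 40 x n_epochs.
channelize_epoch_matrix <- function(x, sampling_rate) {
  n <- nrow(x)
  nb <- n %/% 2L
  k <- seq_len(nb - 1L)
  freq <- k * sampling_rate / n
  keep <- which(freq < 20)
  ch <- floor(freq[keep] / 0.5 + 1e-9)
  n_ep <- ncol(x)
  out <- matrix(0, 40L, n_ep)
  chunk <- 2000L
  for (lo in seq(1L, n_ep, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_ep)
    p <- Mod(stats::mvfft(x[, lo:hi, drop = FALSE]))^2 / n
    sums <- rowsum(p[keep + 1L, , drop = FALSE], group = ch)
    full <- matrix(0, 40L, hi - lo + 1L)
    full[as.integer(rownames(sums)) + 1L, ] <- sums
    out[, lo:hi] <- full
  }
  out
}

#' Build 5-epoch moving-window classifier samples
#'
#' Slides a five-epoch window (stride one) over the per-epoch feature rows
#' and concatenates the five 42-feature vectors in time order into one
#' 210-feature sample per window position, so `n` epochs yield `n - 4`
#' samples. When the features carry a `state` column, each window is
#' labeled with the most common state among its five epochs; a tie (only
#' possible as 2-2-1 with three classes) is broken in favor of the center
#' (third) epoch's state, or, if the center state is not one of the tied
#' leaders, the tied state appearing earliest in the window.
#'
#' @param features Feature tibble from [featurize_recording()] (optionally
#'   with a `state` column).
#'
#' @return Tibble with `center_epoch`, `label` (factor, `NA` when the input
#'   was unlabeled) and feature columns `f001`...`f210`.
#' @export
build_windows <- function(features) {
  feat_cols <- c(sprintf("ch%02d", 0:39), "avg_emg", "activity")
  missing_cols <- setdiff(feat_cols, names(features))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("Feature table lacks columns: %s",
                             paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(features)
  if (n < 5) abort_validation("At least 5 epochs are required to build windows.")
  m <- as.matrix(features[, feat_cols])
  m[is.na(m)] <- 0 # optional channels (e.g. absent activity) enter as 0
  n_win <- n - 4L
  wide <- do.call(cbind, lapply(0:4, function(o) m[(1 + o):(n_win + o), , drop = FALSE]))
  colnames(wide) <- sprintf("f%03d", seq_len(210))

  label <- rep(factor(NA, levels = vigilance_states()), n_win)
  if ("state" %in% names(features)) {
    st <- as.integer(as_state_factor(features$state))
    label <- factor(vigilance_states()[vapply(seq_len(n_win), function(i) {
      window_modal_state(st[i:(i + 4L)])
    }, integer(1))], levels = vigilance_states())
  }
  dplyr::bind_cols(
    tibble::tibble(center_epoch = features$epoch[3:(n - 2L)], label = label),
    tibble::as_tibble(wide)
  )
}

# Modal state of a 5-epoch window (integer codes); 2-2-1 ties go to the
# center epoch's state when it is a tied leader, else the earliest tied
# state in window order.
window_modal_state <- function(s5) {
  counts <- tabulate(s5, nbins = 3)
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(top)
  if (s5[3L] %in% top) return(s5[3L])
  s5[s5 %in% top][1L]
}
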