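# Recording container: raw EEG/EMG sample vectors plus epoch-level channels.
# Kept as a light S3 list (signals are millions of samples, not tabular);
# everything derived from it is a tibble.

new_recording <- function(eeg, emg, sampling_rate, start_zt = 0, epochs = NULL,
                          subject_id = "unknown", treatment_label = "vehicle",
                          prenatal_label = "control") {
  if (length(eeg) != length(emg)) {
    abort_validation("EEG and EMG must have the same number of samples.")
  }
  n_ep <- floor(length(eeg) / (epoch_seconds() * sampling_rate))
  if (is.null(epochs)) {
    epochs <- tibble::tibble(
      epoch = seq_len(n_ep) - 1L,
      zt = zt_of_epoch(seq_len(n_ep) - 1L, start_zt),
      activity = NA_integer_,
      temperature_c = NA_real_
    )
  }
  if (nrow(epochs) != n_ep) {
    abort_validation(sprintf(
      "Epoch table has %d rows but the signals span %d full epochs.",
      nrow(epochs), n_ep
    ))
  }
  structure(
    list(
      eeg = as.numeric(eeg), emg = as.numeric(emg),
      sampling_rate = sampling_rate, start_zt = start_zt,
      epochs = epochs, subject_id = subject_id,
      treatment_label = treatment_label, prenatal_label = prenatal_label
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %s (%s, %s): %.1f s of EEG/EMG at %g Hz, start ZT %g, %d epochs\n",
    x$subject_id, x$treatment_label, x$prenatal_label,
    length(x$eeg) / x$sampling_rate, x$sampling_rate, x$start_zt, nrow(x$epochs)
  ))
  invisible(x)
}

# Duration in seconds.
recording_duration_s <- function(recording) {
  length(recording$eeg) / recording$sampling_rate
}
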