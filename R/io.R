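# European Data Format (EDF) codec for the two waveform channels, written
# from the published header layout: 256-byte fixed header + 256 bytes per
# signal, then int16 little-endian data records. One data record per second;
# EEG and EMG each contribute `sampling_rate` samples per record. Epoch-level
# channels (activity, temperature, truth labels) travel in a tab-separated
# sidecar because their 0.1 Hz effective rate fits EDF awkwardly.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) edf_pad(format(x, trim = TRUE, scientific = FALSE), width)

#' Write a recording to EDF plus an epoch sidecar
#'
#' Writes `<prefix>.edf` (EEG and EMG, 16-bit, one data record per second)
#' and `<prefix>_epochs.tsv` (columns `epoch_index`, `zt_start_s`,
#' `activity`, `temperature_c`, and `state` when truth labels are
#' available). Both files are written atomically (temp file + rename).
#' Signals are quantized to the 16-bit digital range scaled to each
#' channel's physical extremes, so a round trip reproduces samples to
#' within one quantization step.
#'
#' @param x A `recording` or `simulated_recording` (whose truth hypnogram is
#'   then written into the sidecar).
#' @param prefix Output path prefix (directory must exist).
#' @param hypnogram Optional hypnogram tibble overriding/adding sidecar
#'   labels.
#'
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(x, prefix, hypnogram = NULL) {
  if (inherits(x, "simulated_recording")) {
    if (is.null(hypnogram)) hypnogram <- x$hypnogram
    x <- x$recording
  }
  stopifnot(inherits(x, "recording"))
  sr <- x$sampling_rate
  if (abs(sr - round(sr)) > 1e-9) {
    abort_validation("EDF export needs an integer sampling rate (1-s records).")
  }
  sr <- as.integer(round(sr))
  n_rec <- floor(length(x$eeg) / sr)
  if (n_rec < 1) abort_validation("Recording shorter than one 1-s data record.")

  sig <- list(EEG = x$eeg[seq_len(n_rec * sr)], EMG = x$emg[seq_len(n_rec * sr)])
  pmax_ <- vapply(sig, function(s) max(1e-6, max(abs(s))), numeric(1))
  dmin <- -32768L; dmax <- 32767L

  recording_id <- sprintf(
    "somnoscore subject=%s treatment=%s prenatal=%s start_zt=%g",
    x$subject_id, x$treatment_label, x$prenatal_label, x$start_zt
  )
  header <- paste0(
    edf_pad("0", 8),
    edf_pad(x$subject_id, 80),
    edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(256 + 2 * 256, 8),
    edf_pad("", 44),
    edf_num(n_rec, 8),
    edf_num(1, 8),
    edf_num(2, 4),
    # per-signal fields, each field for all signals in turn
    edf_pad("EEG", 16), edf_pad("EMG", 16),
    edf_pad("", 80), edf_pad("", 80),
    edf_pad("uV", 8), edf_pad("uV", 8),
    edf_num(-pmax_[["EEG"]], 8), edf_num(-pmax_[["EMG"]], 8),
    edf_num(pmax_[["EEG"]], 8), edf_num(pmax_[["EMG"]], 8),
    edf_num(dmin, 8), edf_num(dmin, 8),
    edf_num(dmax, 8), edf_num(dmax, 8),
    edf_pad("", 80), edf_pad("", 80),
    edf_num(sr, 8), edf_num(sr, 8),
    edf_pad("", 32), edf_pad("", 32)
  )

  digital <- lapply(names(sig), function(nm) {
    s <- sig[[nm]]
    d <- round((s - (-pmax_[[nm]])) / (2 * pmax_[[nm]]) * (dmax - dmin) + dmin)
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  # Interleave per record: EEG block then EMG block.
  idx <- matrix(seq_len(n_rec * sr), nrow = sr)
  interleaved <- integer(2 * n_rec * sr)
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * 2L * sr
    interleaved[base + seq_len(sr)] <- digital[[1]][idx[, r]]
    interleaved[base + sr + seq_len(sr)] <- digital[[2]][idx[, r]]
  }

  edf_path <- paste0(prefix, ".edf")
  tmp <- tempfile(tmpdir = dirname(edf_path))
  con <- file(tmp, "wb")
  writeChar(header, con, eos = NULL)
  writeBin(interleaved, con, size = 2, endian = "little")
  close(con)
  file.rename(tmp, edf_path)

  n_ep <- nrow(x$epochs)
  side <- tibble::tibble(
    epoch_index = x$epochs$epoch,
    zt_start_s = round(x$epochs$zt * 3600, 3),
    activity = x$epochs$activity,
    temperature_c = x$epochs$temperature_c
  )
  if (!is.null(hypnogram)) {
    st <- hypnogram_states(hypnogram)
    if (length(st) != n_ep) {
      abort_validation(sprintf(
        "Hypnogram has %d labels for %d epochs.", length(st), n_ep
      ))
    }
    side$state <- as.character(st)
  }
  write_table_atomic(side, paste0(prefix, "_epochs.tsv"), delim = "\t")
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' Parses the EDF header and 16-bit data records for the EEG and EMG
#' channels, restores physical units from the scaling fields, and joins the
#' epoch sidecar. A sidecar whose row count disagrees with the number of
#' full 10-s epochs in the signals is an error; an absent `temperature_c`
#' or `activity` column is tolerated (values become missing).
#'
#' @param prefix Path prefix used when writing.
#'
#' @return A `recording`; when the sidecar carries truth labels, the
#'   hypnogram tibble is attached as field `hypnogram`.
#' @export
read_recording <- function(prefix) {
  edf_path <- paste0(prefix, ".edf")
  side_path <- paste0(prefix, "_epochs.tsv")
  if (!file.exists(edf_path)) abort_validation(sprintf("No EDF at %s.", edf_path))
  con <- file(edf_path, "rb")
  on.exit(close(con), add = TRUE)
  head_fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(head_fixed, type = "bytes") < 256) {
    abort_validation("Unreadable EDF header (truncated).")
  }
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(fld(head_fixed, 237, 8))
  rec_dur <- as.numeric(fld(head_fixed, 245, 8))
  ns <- as.integer(fld(head_fixed, 253, 4))
  if (is.na(ns) || ns < 2) abort_validation("EDF must contain at least EEG and EMG signals.")
  sig_head <- readChar(con, 256 * ns, useBytes = TRUE)
  seg <- function(block, i, width) {
    offset <- switch(block, label = 0, transducer = 16 * ns,
                     dim = 96 * ns, pmin = 104 * ns, pmax = 112 * ns,
                     dmin = 120 * ns, dmax = 128 * ns, prefilter = 136 * ns,
                     nsamp = 216 * ns, reserved = 224 * ns)
    trimws(substr(sig_head, offset + (i - 1) * width + 1, offset + i * width))
  }
  labels <- toupper(vapply(seq_len(ns), function(i) seg("label", i, 16), character(1)))
  i_eeg <- match("EEG", labels)
  i_emg <- match("EMG", labels)
  if (is.na(i_eeg) || is.na(i_emg)) {
    abort_validation("EDF lacks channels labeled EEG and EMG.")
  }
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) seg("pmin", i, 8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) seg("pmax", i, 8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) seg("dmin", i, 8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) seg("dmax", i, 8), character(1)))
  nsamp <- as.integer(vapply(seq_len(ns), function(i) seg("nsamp", i, 8), character(1)))

  raw <- readBin(con, integer(), n = n_rec * sum(nsamp), size = 2,
                 endian = "little")
  per_rec <- sum(nsamp)
  starts <- c(0L, cumsum(nsamp))
  take <- function(i) {
    off <- rep((seq_len(n_rec) - 1L) * per_rec, each = nsamp[i]) +
      starts[i] + seq_len(nsamp[i])
    d <- raw[off]
    (d - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
  }
  eeg <- take(i_eeg)
  emg <- take(i_emg)
  sr <- nsamp[i_eeg] / rec_dur

  rid <- fld(head_fixed, 89, 80)
  meta <- function(key, default) {
    m <- regmatches(rid, regexec(paste0(key, "=([^ ]+)"), rid))[[1]]
    if (length(m) == 2) m[2] else default
  }
  start_zt <- as.numeric(meta("start_zt", "0"))

  side <- utils::read.delim(side_path, sep = "\t", check.names = FALSE)
  n_ep <- floor(length(eeg) / (epoch_seconds() * sr))
  if (nrow(side) != n_ep) {
    abort_validation(sprintf(
      "Sidecar has %d rows but the EDF spans %d full epochs.", nrow(side), n_ep
    ))
  }
  epochs <- tibble::tibble(
    epoch = as.integer(side$epoch_index),
    zt = side$zt_start_s / 3600,
    activity = if ("activity" %in% names(side)) as.integer(side$activity) else NA_integer_,
    temperature_c = if ("temperature_c" %in% names(side)) side$temperature_c else NA_real_
  )
  rec <- new_recording(
    eeg = eeg, emg = emg, sampling_rate = sr, start_zt = start_zt,
    epochs = epochs,
    subject_id = meta("subject", fld(head_fixed, 9, 80)),
    treatment_label = meta("treatment", "vehicle"),
    prenatal_label = meta("prenatal", "control")
  )
  if ("state" %in% names(side)) {
    rec$hypnogram <- tibble::tibble(
      epoch = epochs$epoch, zt = epochs$zt,
      state = as_state_factor(side$state)
    )
  }
  rec
}

# Atomic delimited-text writer shared by all table outputs.
write_table_atomic <- function(df, path, delim = ",") {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = delim, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read/write hypnograms and feature tables as delimited text
#'
#' Hypnograms are CSV with columns `epoch_index`, `zt`, `state`; feature
#' tables are CSV with `epoch_index`, `zt`, `ch00`...`ch39`, `avg_emg`,
#' `activity` and optionally `state`.
#'
#' @param hypnogram,features Tibbles as produced by the package.
#' @param path File path.
#' @return The read tibble, or the path invisibly for writers.
#' @export
write_hypnogram <- function(hypnogram, path) {
  st <- hypnogram_states(hypnogram)
  df <- tibble::tibble(
    epoch_index = if ("epoch" %in% names(hypnogram)) hypnogram$epoch else seq_along(st) - 1L,
    zt = if ("zt" %in% names(hypnogram)) hypnogram$zt else
      zt_of_epoch(seq_along(st) - 1L, 0),
    state = as.character(st)
  )
  write_table_atomic(df, path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tibble::tibble(
    epoch = as.integer(df$epoch_index),
    zt = df$zt,
    state = as_state_factor(df$state)
  )
}

#' @rdname write_hypnogram
#' @export
write_features <- function(features, path) {
  df <- features
  names(df)[names(df) == "epoch"] <- "epoch_index"
  write_table_atomic(df, path)
}

#' @rdname write_hypnogram
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[names(df) == "epoch_index"] <- "epoch"
  out <- tibble::as_tibble(df)
  if ("state" %in% names(out)) out$state <- as_state_factor(out$state)
  out
}

#' Save / load a trained classifier bundle
#'
#' The bundle is a single portable RDS file holding the architecture,
#' weights, standardization constants, training history and a hash of the
#' featurization settings, so a loaded model refuses feature tables of the
#' wrong shape.
#'
#' @param model A `vigilance_mlp`.
#' @param path File path (conventionally `.rds`).
#' @return The model (readers) or the path invisibly (writers).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "vigilance_mlp"))
  bundle <- list(
    format = "somnoscore_mlp_v1",
    model = model,
    feature_hash = rlang::hash(list(
      n_channels = 40, window = 5, epoch_s = epoch_seconds()
    ))
  )
  tmp <- tempfile(tmpdir = dirname(path))
  saveRDS(bundle, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "somnoscore_mlp_v1")) {
    abort_validation("Not a somnoscore model bundle.")
  }
  bundle$model
}
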