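#' Detect bouts (maximal same-state runs) in a hypnogram
#'
#' An uninterrupted episode of a single vigilance state lasting at least one
#' full epoch is a bout, so bouts are exactly the maximal runs of the label
#' sequence and every epoch belongs to exactly one bout.
#'
#' @param hypnogram Hypnogram tibble (columns `epoch`, `zt`, `state`) or a
#'   bare state vector.
#'
#' @return Tibble with one row per bout: `state`, `start_epoch` (0-based),
#'   `length_epochs`, `duration_s`.
#' @export
#' @examples
#' detect_bouts(c("W", "W", "N", "N", "N", "R", "R", "W"))
detect_bouts <- function(hypnogram) {
  st <- hypnogram_states(expand_abbrev(hypnogram))
  r <- rle(as.integer(st))
  start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  tibble::tibble(
    state = factor(vigilance_states()[r$values], levels = vigilance_states()),
    start_epoch = start,
    length_epochs = r$lengths,
    duration_s = r$lengths * epoch_seconds()
  )
}

# Allow single-letter W/N/R shorthands in bare vectors (handy in examples
# and tests); full tibbles pass through untouched.
expand_abbrev <- function(x) {
  if (is.data.frame(x)) return(x)
  y <- toupper(as.character(x))
  map <- c(W = "WAKE", N = "NREM", R = "REM")
  y[y %in% names(map)] <- map[y[y %in% names(map)]]
  y
}

#' Count scored transitions between vigilance states, per phase
#'
#' A transition is scored only when two or more consecutive epochs carry the
#' new vigilance state. Operationally: a current scored state (initialized
#' to the first run's state) is carried along the run-length encoding; a run
#' of length >= 2 whose state differs from the current scored state scores
#' one transition (current -> run state) and becomes the new current state,
#' while single-epoch runs never score a transition and never update the
#' current state. Each transition is attributed to the phase (light/dark) of
#' the first epoch of the new state's run.
#'
#' @param hypnogram Hypnogram tibble or state vector.
#' @param schedule A [light_dark_schedule()].
#'
#' @return Tibble with columns `phase`, `from`, `to`, `n` covering all six
#'   ordered state pairs in both phases.
#' @export
#' @examples
#' count_transitions(c("N", "N", "W", "N", "N")) # lone W never scores
count_transitions <- function(hypnogram, schedule = light_dark_schedule()) {
  st <- hypnogram_states(expand_abbrev(hypnogram))
  start_zt <- hypnogram_start_zt(hypnogram)
  bouts <- detect_bouts(hypnogram)

  lv <- vigilance_states()
  pairs <- expand.grid(from = lv, to = lv, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  counts <- tidyr::expand_grid(
    phase = factor(c("light", "dark"), levels = c("light", "dark")),
    tibble::as_tibble(pairs)
  )
  counts$n <- 0L

  current <- as.character(bouts$state[1])
  if (nrow(bouts) > 1) {
    for (i in 2:nrow(bouts)) {
      if (bouts$length_epochs[i] >= 2 && as.character(bouts$state[i]) != current) {
        ph <- as.character(phase_of_zt(
          zt_of_epoch(bouts$start_epoch[i], start_zt, schedule$period), schedule
        ))
        hit <- counts$phase == ph & counts$from == current &
          counts$to == as.character(bouts$state[i])
        counts$n[hit] <- counts$n[hit] + 1L
        current <- as.character(bouts$state[i])
      }
    }
  }
  counts$from <- factor(counts$from, levels = lv)
  counts$to <- factor(counts$to, levels = lv)
  counts
}

#' Sleep onset latency within a 12-h phase
#'
#' Minutes from the phase start to the first epoch of the first run of at
#' least two consecutive epochs of the target state at or after the phase
#' start. Returns `NA` (flagged with a message) when no qualifying run
#' exists in the recording after the phase start.
#'
#' @param hypnogram Hypnogram tibble or state vector (assumed to start at
#'   ZT 0 when a bare vector).
#' @param state `"NREM"` or `"REM"`.
#' @param phase_start_zt ZT (hours) the latency is measured from, typically
#'   0 or 12 (= injection time in a dosing experiment).
#'
#' @return Latency in minutes (single number), or `NA` if absent.
#' @export
onset_latency <- function(hypnogram, state = c("NREM", "REM"), phase_start_zt = 0) {
  state <- match.arg(state)
  st <- hypnogram_states(expand_abbrev(hypnogram))
  start_zt <- hypnogram_start_zt(hypnogram)
  epoch_zt_h <- epoch_seconds() / 3600
  # First epoch index at or after the phase start.
  offset_h <- (phase_start_zt - start_zt) %% 24
  first_epoch <- ceiling(offset_h / epoch_zt_h - 1e-9)
  if (first_epoch >= length(st)) {
    abort_validation("Phase start lies outside the recording.")
  }
  bouts <- detect_bouts(hypnogram)
  ok <- bouts$state == state & bouts$length_epochs >= 2 &
    bouts$start_epoch >= first_epoch
  if (!any(ok)) {
    message(sprintf("No >=2-epoch %s run at or after ZT %g; onset is missing.",
                    state, phase_start_zt))
    return(NA_real_)
  }
  (min(bouts$start_epoch[ok]) - first_epoch) * epoch_seconds() / 60
}

#' Binned state durations, bout counts and mean bout durations
#'
#' Splits the hypnogram into consecutive 1-h or 6-h bins (anchored at the
#' recording start; a trailing partial bin is dropped with a warning) and
#' reports, per bin and state: total duration in minutes (10/60 min per
#' epoch), the number of bouts whose first epoch lies in the bin, and the
#' mean duration of those bouts. Bouts straddling a bin edge are counted
#' once, at full length, in the bin where they start.
#'
#' @param hypnogram Hypnogram tibble or state vector.
#' @param bin_hours Bin width: 1 or 6.
#' @param schedule A [light_dark_schedule()].
#'
#' @return Tibble with `bin`, `bin_start_zt`, `phase`, `state`, `minutes`,
#'   `bout_count`, `mean_bout_s` (NA where a state has no bouts starting in
#'   the bin).
#' @export
bin_durations <- function(hypnogram, bin_hours = 1, schedule = light_dark_schedule()) {
  if (!bin_hours %in% c(1, 6)) {
    abort_validation("`bin_hours` must be 1 or 6.")
  }
  st <- hypnogram_states(expand_abbrev(hypnogram))
  start_zt <- hypnogram_start_zt(hypnogram)
  per_bin <- as.integer(bin_hours * 3600 / epoch_seconds())
  n_bins <- length(st) %/% per_bin
  if (n_bins == 0) abort_validation("Hypnogram shorter than one bin.")
  if (length(st) %% per_bin != 0) {
    warning(sprintf("Dropping %d trailing epoch(s) (partial %g-h bin).",
                    length(st) %% per_bin, bin_hours))
    st <- st[seq_len(n_bins * per_bin)]
  }

  epoch_bin <- rep(seq_len(n_bins) - 1L, each = per_bin)
  dur <- tibble::tibble(bin = epoch_bin, state = st) |>
    dplyr::count(.data$bin, .data$state, .drop = FALSE) |>
    dplyr::mutate(minutes = .data$n * epoch_seconds() / 60) |>
    dplyr::select(-"n")

  bouts <- detect_bouts(st) |>
    dplyr::mutate(bin = .data$start_epoch %/% per_bin) |>
    dplyr::filter(.data$bin < n_bins) |>
    dplyr::group_by(.data$bin, .data$state) |>
    dplyr::summarise(
      bout_count = dplyr::n(),
      mean_bout_s = mean(.data$duration_s),
      .groups = "drop"
    )

  dur |>
    dplyr::left_join(bouts, by = c("bin", "state")) |>
    dplyr::mutate(
      bout_count = dplyr::coalesce(.data$bout_count, 0L),
      bin_start_zt = zt_of_epoch(.data$bin * per_bin, start_zt, schedule$period),
      phase = phase_of_zt(.data$bin_start_zt, schedule)
    ) |>
    dplyr::select("bin", "bin_start_zt", "phase", "state", "minutes",
                  "bout_count", "mean_bout_s") |>
    dplyr::arrange(.data$bin, .data$state)
}

#' Percent change from vehicle, per bin and state
#'
#' For matched treated and vehicle architecture tables (same subject, same
#' bin grid), computes 100 x (treated - vehicle) / vehicle for the chosen
#' metric in every bin/state cell. Cells with a zero vehicle value are
#' flagged undefined (`NA`), never returned as infinite.
#'
#' @param treated,vehicle Tibbles from [bin_durations()] on the same bin
#'   grid.
#' @param metric Column to compare, default `"minutes"`.
#'
#' @return Tibble `bin`, `bin_start_zt`, `phase`, `state`, `vehicle`,
#'   `treated`, `percent_change`, `undefined`.
#' @export
#' @examples
#' # 71 min of sleep against a 60-min vehicle baseline is +18.3%
#' 100 * (71 - 60) / 60
percent_change <- function(treated, vehicle, metric = "minutes") {
  j <- join_summaries(treated, vehicle, metric)
  j$percent_change <- ifelse(j$vehicle == 0, NA_real_,
                             100 * (j$treated - j$vehicle) / j$vehicle)
  j$undefined <- j$vehicle == 0
  j
}

#' Absolute (within-subject) change from vehicle
#'
#' As [percent_change()] but in the metric's native units:
#' treated - vehicle per bin and state. Anti-symmetric under argument swap.
#'
#' @inheritParams percent_change
#' @return Tibble `bin`, `bin_start_zt`, `phase`, `state`, `vehicle`,
#'   `treated`, `absolute_change`.
#' @export
absolute_change <- function(treated, vehicle, metric = "minutes") {
  j <- join_summaries(treated, vehicle, metric)
  j$absolute_change <- j$treated - j$vehicle
  j
}

join_summaries <- function(treated, vehicle, metric) {
  for (tab in list(treated, vehicle)) {
    if (!all(c("bin", "state", metric) %in% names(tab))) {
      abort_validation(sprintf(
        "Summaries must carry `bin`, `state` and `%s` columns.", metric
      ))
    }
  }
  if (nrow(treated) != nrow(vehicle) ||
      !identical(treated$bin, vehicle$bin) ||
      !identical(as.character(treated$state), as.character(vehicle$state))) {
    abort_validation("Treated and vehicle summaries are not on matched bins.")
  }
  keep <- intersect(c("bin", "bin_start_zt", "phase", "state"), names(treated))
  out <- treated[, keep]
  out$vehicle <- vehicle[[metric]]
  out$treated <- treated[[metric]]
  tibble::as_tibble(out)
}

#' Full architecture summary for one hypnogram
#'
#' Bundles the binned durations (1-h and 6-h), per-phase onset latencies and
#' per-phase transition counts into one list, mirroring the quantities a
#' sleep-architecture analysis consumes downstream.
#'
#' @param hypnogram Hypnogram tibble.
#' @param schedule A [light_dark_schedule()].
#'
#' @return Named list: `bins_1h`, `bins_6h`, `onsets` (tibble phase x state),
#'   `transitions`.
#' @export
architecture_summary <- function(hypnogram, schedule = light_dark_schedule()) {
  start_zt <- hypnogram_start_zt(hypnogram)
  phases <- tibble::tibble(
    phase = factor(c("light", "dark"), levels = c("light", "dark")),
    phase_start_zt = c(schedule$lights_on_zt, schedule$lights_off_zt)
  )
  onsets <- tidyr::expand_grid(phases, state = c("NREM", "REM")) |>
    dplyr::rowwise() |>
    dplyr::mutate(onset_min = suppressMessages(
      onset_latency(hypnogram, .data$state, .data$phase_start_zt)
    )) |>
    dplyr::ungroup()
  list(
    bins_1h = bin_durations(hypnogram, 1, schedule),
    bins_6h = bin_durations(hypnogram, 6, schedule),
    onsets = onsets,
    transitions = count_transitions(hypnogram, schedule)
  )
}
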