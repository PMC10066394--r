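#' End-to-end two-arm virtual experiment
#'
#' Runs the whole pipeline on a simulated within-subject crossover: one
#' vehicle arm and one drug arm (treatment applied from ZT 0, emulating
#' dosing at lights-on), sharing the same seed so the arms differ only by
#' the treatment knobs. Steps: simulate both arms, featurize, train the
#' MLP on the vehicle arm's labeled windows (stratified split, oversampled
#' training classes), score both arms into predicted hypnograms, then
#' compute the derived metrics a sleep-pharmacology analysis consumes:
#' 6-h-binned durations with percent and absolute change from vehicle,
#' onset latencies, transition counts, and the light-phase NREM spectral
#' contrast.
#'
#' @param seed Master seed; one integer drives every stage.
#' @param duration_h Length of each arm's recording, hours. Default 24.
#' @param treatment [treatment_effect()] for the drug arm.
#' @param classifier_config [mlp_config()] for the scorer.
#' @param sampling_rate Hz.
#' @param out_dir Optional directory; when given, hypnograms, summaries,
#'   spectra and the model bundle are written there (atomically, with the
#'   config hash and seed embedded in a provenance file).
#' @param use_truth_labels Score architecture/spectra on the truth
#'   hypnograms instead of the classifier's predictions (default FALSE:
#'   predictions, the end-to-end path).
#'
#' @return Named list: `evaluation` (held-out classifier metrics),
#'   `percent_change_6h`, `absolute_change_6h`, `phase_change`
#'   (light/dark-phase totals), `delta_contrast` (light-phase NREM spectral
#'   contrast), `onsets`, `transitions`, `hypnograms`, `seed`,
#'   `config_hash`.
#' @export
run_demo <- function(seed = 1,
                     duration_h = 24,
                     treatment = treatment_effect(),
                     classifier_config = mlp_config(seed = seed),
                     sampling_rate = 250,
                     out_dir = NULL,
                     use_truth_labels = FALSE) {
  schedule <- light_dark_schedule()
  arms <- list(
    vehicle = simulate_recording(
      duration_h = duration_h, seed = seed, sampling_rate = sampling_rate,
      subject_id = "demo", treatment = NULL
    ),
    drug = simulate_recording(
      duration_h = duration_h, seed = seed, sampling_rate = sampling_rate,
      subject_id = "demo", treatment = treatment
    )
  )
  feats <- lapply(arms, function(a) featurize_recording(a$recording, a$hypnogram))

  windows <- split_windows(build_windows(feats$vehicle),
                           fractions = classifier_config$split_fractions,
                           seed = seed)
  train <- windows[windows$split == "train", ]
  if (classifier_config$oversample) train <- oversample_training(train, seed = seed)
  model <- fit_vigilance_mlp(train, windows[windows$split == "validation", ],
                             classifier_config)
  evaluation <- evaluate_classifier(model, windows[windows$split == "test", ])

  hyps <- if (use_truth_labels) {
    lapply(arms, function(a) a$hypnogram)
  } else {
    lapply(feats, function(f) predict_hypnogram(model, f))
  }

  bins <- lapply(hyps, bin_durations, bin_hours = 6, schedule = schedule)
  pc <- percent_change(bins$drug, bins$vehicle)
  ac <- absolute_change(bins$drug, bins$vehicle)

  phase_tot <- function(h) {
    bin_durations(h, 6, schedule) |>
      dplyr::group_by(.data$phase, .data$state) |>
      dplyr::summarise(minutes = sum(.data$minutes), .groups = "drop")
  }
  pv <- phase_tot(hyps$vehicle)
  pt <- phase_tot(hyps$drug)
  phase_change <- pv |>
    dplyr::rename(vehicle = "minutes") |>
    dplyr::mutate(
      treated = pt$minutes,
      percent_change = ifelse(.data$vehicle == 0, NA_real_,
                              100 * (.data$treated - .data$vehicle) / .data$vehicle)
    )

  spec_v <- state_phase_spectrum(feats$vehicle, hyps$vehicle, "NREM", "light", schedule)
  spec_d <- state_phase_spectrum(feats$drug, hyps$drug, "NREM", "light", schedule)
  delta_contrast <- spectral_contrast(spec_d, spec_v)

  onsets <- dplyr::bind_rows(
    vehicle = architecture_summary(hyps$vehicle, schedule)$onsets,
    drug = architecture_summary(hyps$drug, schedule)$onsets,
    .id = "arm"
  )
  transitions <- dplyr::bind_rows(
    vehicle = count_transitions(hyps$vehicle, schedule),
    drug = count_transitions(hyps$drug, schedule),
    .id = "arm"
  )

  cfg <- run_config(seed = seed, duration_h = duration_h,
                    sampling_rate = sampling_rate, out_dir = out_dir,
                    treatment = treatment, classifier = classifier_config)
  out <- list(
    evaluation = evaluation,
    percent_change_6h = pc,
    absolute_change_6h = ac,
    phase_change = phase_change,
    delta_contrast = delta_contrast,
    onsets = onsets,
    transitions = transitions,
    hypnograms = hyps,
    seed = seed,
    config_hash = config_hash(cfg)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hypnogram(hyps$vehicle, file.path(out_dir, "hypnogram_vehicle.csv"))
    write_hypnogram(hyps$drug, file.path(out_dir, "hypnogram_drug.csv"))
    write_table_atomic(pc, file.path(out_dir, "percent_change_6h.csv"))
    write_table_atomic(ac, file.path(out_dir, "absolute_change_6h.csv"))
    write_table_atomic(phase_change, file.path(out_dir, "phase_change.csv"))
    write_table_atomic(delta_contrast, file.path(out_dir, "nrem_delta_contrast_light.csv"))
    write_table_atomic(onsets, file.path(out_dir, "onsets.csv"))
    write_table_atomic(transitions, file.path(out_dir, "transitions.csv"))
    write_model(model, file.path(out_dir, "model.rds"))
    write_table_atomic(
      tibble::tibble(seed = seed, config_hash = out$config_hash,
                     accuracy = evaluation$accuracy),
      file.path(out_dir, "provenance.csv")
    )
  }
  out
}
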