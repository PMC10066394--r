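test_that("epoch segmentation floors to whole 10-s epochs and tracks ZT", {
  rec_3600 <- somnoscore:::new_recording(
    eeg = rnorm(3600 * 100), emg = rnorm(3600 * 100), sampling_rate = 100
  )
  expect_equal(nrow(segment_epochs(rec_3600)), 360L)

  rec_3605 <- somnoscore:::new_recording(
    eeg = rnorm(3605 * 100), emg = rnorm(3605 * 100), sampling_rate = 100
  )
  expect_message(eps <- segment_epochs(rec_3605), "partial")
  expect_equal(nrow(eps), 360L)

  # Starting at ZT 11.9 h, epoch 37 (370 s in) has crossed lights-off.
  rec_dark <- somnoscore:::new_recording(
    eeg = rnorm(400 * 100), emg = rnorm(400 * 100), sampling_rate = 100,
    start_zt = 11.9
  )
  eps <- segment_epochs(rec_dark)
  expect_lt(eps$zt[eps$epoch == 35], 12)
  expect_gte(eps$zt[eps$epoch == 37], 12)
  expect_equal(as.character(phase_of_zt(eps$zt[eps$epoch == 37])), "dark")

  short <- somnoscore:::new_recording(eeg = rnorm(500), emg = rnorm(500),
                                      sampling_rate = 100)
  expect_error(segment_epochs(short), class = "somnoscore_validation_error")
})

test_that("every epoch yields exactly 42 features and fractions sum to 1", {
  sim <- shared_sim()
  f <- featurize_recording(sim$recording, sim$hypnogram)
  ch_cols <- grep("^ch[0-9]{2}$", names(f), value = TRUE)
  expect_length(ch_cols, 40L)
  expect_true(all(c("avg_emg", "activity") %in% names(f)))
  expect_equal(length(ch_cols) + 2L, 42L)
  sums <- rowSums(as.matrix(f[, ch_cols]))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(as.matrix(f[, ch_cols]) >= 0))

  # Feature count is sampling-rate independent.
  sim2 <- simulate_recording(duration_h = 1 / 6, seed = 2, sampling_rate = 100)
  f2 <- featurize_recording(sim2$recording)
  expect_length(grep("^ch[0-9]{2}$", names(f2)), 40L)
})

test_that("a pure 6.1 Hz tone lands in the [6.0, 6.5) channel", {
  sr <- 250
  t <- seq(0, 10 - 1 / sr, by = 1 / sr)
  rec <- somnoscore:::new_recording(
    eeg = sin(2 * pi * 6.1 * t), emg = rnorm(length(t)), sampling_rate = sr
  )
  f <- featurize_recording(rec)
  expect_gte(f$ch12[1], 0.99)
})

test_that("white-noise EEG gives near-flat channel fractions (100-epoch mean)", {
  sr <- 250
  withr::with_seed(31, {
    rec <- somnoscore:::new_recording(
      eeg = rnorm(100 * 10 * sr), emg = rnorm(100 * 10 * sr), sampling_rate = sr
    )
  })
  f <- featurize_recording(rec)
  means <- colMeans(as.matrix(f[, sprintf("ch%02d", 0:39)]))
  # Closed-form flat-spectrum expectation: 199 periodogram bins below 20 Hz
  # (DC excluded), of which channel 0 holds 4 and every other channel 5.
  expected <- c(4, rep(5, 39)) / 199
  expect_true(all(abs(means - expected) < 0.005))
  # The five-bin channels are also within 0.005 of the nominal 1/40.
  expect_true(all(abs(means[-1] - 1 / 40) < 0.005))
})

test_that("un-normalized channel powers obey Parseval over [0, 20) Hz", {
  # Band-limited synthetic EEG (no DC, no power at/above 20 Hz), so the
  # one-sided channel sum must equal half the time-domain energy sum(x^2),
  # divided by n: total = sum(x^2)/2 with the periodogram scaling |X|^2/n.
  h <- str_hyp("NRWN")
  rec <- synthesize_signals(h, seed = 6)
  n <- 2500
  for (i in 1:4) {
    x <- rec$eeg[(i - 1) * n + 1:n]
    ch <- somnoscore:::epoch_channel_power(x, 250)
    expect_equal(sum(ch), sum(x^2) / 2, tolerance = 1e-6)
  }
})

test_that("channel fractions are invariant to EEG amplitude scaling", {
  sim <- shared_sim()
  f1 <- featurize_recording(sim$recording)
  rec2 <- sim$recording
  rec2$eeg <- rec2$eeg * 37.5
  f2 <- featurize_recording(rec2)
  ch <- sprintf("ch%02d", 0:39)
  expect_equal(as.matrix(f1[, ch]), as.matrix(f2[, ch]), tolerance = 1e-12)
})

test_that("constant-amplitude EMG reports its amplitude as avg_emg", {
  sr <- 100
  rec <- somnoscore:::new_recording(
    eeg = rnorm(10 * sr), emg = rep(2.5, 10 * sr), sampling_rate = sr
  )
  f <- featurize_recording(rec)
  expect_equal(f$avg_emg, 2.5)
})

test_that("NaN samples raise an error naming the epoch; zero power warns", {
  sr <- 100
  eeg <- rnorm(30 * sr)
  eeg[1500] <- NaN # inside epoch index 1
  rec <- somnoscore:::new_recording(eeg = eeg, emg = rnorm(30 * sr), sampling_rate = sr)
  expect_error(featurize_recording(rec), regexp = "epoch.*1",
               class = "somnoscore_validation_error")

  flat <- somnoscore:::new_recording(
    eeg = rep(0, 10 * sr), emg = rnorm(10 * sr), sampling_rate = sr
  )
  expect_warning(fz <- featurize_recording(flat), regexp = "zero total")
  expect_true(all(as.matrix(fz[, sprintf("ch%02d", 0:39)]) == 0))
})

test_that("five-epoch windows concatenate 210 features with modal labels", {
  sim <- shared_sim()
  f <- featurize_recording(sim$recording, sim$hypnogram)
  w <- build_windows(f)
  expect_equal(nrow(w), nrow(f) - 4L)
  expect_length(grep("^f[0-9]{3}$", names(w)), 210L)
  # Window features really are the five consecutive epoch vectors in order.
  feat_cols <- c(sprintf("ch%02d", 0:39), "avg_emg", "activity")
  expect_equal(as.numeric(w[1, sprintf("f%03d", 1:210)]),
               as.vector(t(as.matrix(f[1:5, feat_cols]))))
  expect_error(build_windows(f[1:4, ]), class = "somnoscore_validation_error")
})

test_that("window labels follow majority vote with center-epoch tie-breaks", {
  lab_of <- function(s) {
    f <- featurize_recording(synthesize_signals(str_hyp(s), seed = 1), str_hyp(s))
    as.character(build_windows(f)$label[1])
  }
  expect_equal(lab_of("WWNNN"), "NREM") # clear majority
  expect_equal(lab_of("WWNNR"), "NREM") # 2-2-1 tie, center epoch is NREM
  expect_equal(lab_of("WWRNN"), "WAKE") # 2-2-1 tie, center not tied: earliest
  expect_equal(lab_of("RRRRR"), "REM")
})

test_that("24 hours of epochs yield n - 4 window samples", {
  # Label bookkeeping only; features are tiny white noise for speed.
  n <- 8640
  withr::with_seed(8, {
    f <- tibble::as_tibble(matrix(runif(n * 40), n, 40,
                                  dimnames = list(NULL, sprintf("ch%02d", 0:39))))
  })
  f <- dplyr::bind_cols(
    tibble::tibble(epoch = 0:(n - 1), zt = somnoscore:::zt_of_epoch(0:(n - 1), 0)),
    f, tibble::tibble(avg_emg = 1, activity = 0)
  )
  expect_equal(nrow(build_windows(f)), 8636L)
})
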