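test_that("bout detection matches hand-worked run-length examples", {
  b <- detect_bouts(c("W", "W", "N", "N", "N", "R", "R", "W"))
  expect_equal(nrow(b), 4L)
  expect_equal(as.character(b$state), c("WAKE", "NREM", "REM", "WAKE"))
  expect_equal(b$length_epochs, c(2L, 3L, 2L, 1L))
  expect_equal(b$duration_s, c(20, 30, 20, 10))
  expect_equal(b$start_epoch, c(0L, 2L, 5L, 7L))

  one <- detect_bouts(rep("NREM", 17))
  expect_equal(nrow(one), 1L)
  expect_equal(one$length_epochs, 17L)

  alt <- detect_bouts(c("W", "N", "W", "N"))
  expect_equal(nrow(alt), 4L)
  expect_true(all(alt$length_epochs == 1L))
})

test_that("transition scoring requires two epochs of the new state", {
  tc <- count_transitions(c("W", "W", "N", "N", "N", "R", "R", "W"))
  get <- function(from, to) sum(tc$n[tc$from == from & tc$to == to])
  expect_equal(get("WAKE", "NREM"), 1L)
  expect_equal(get("NREM", "REM"), 1L)
  expect_equal(get("REM", "WAKE"), 0L) # final wake run is a single epoch
  expect_equal(sum(tc$n), 2L)

  # A lone interrupting epoch neither scores nor resets the scored state.
  expect_equal(sum(count_transitions(c("N", "N", "W", "N", "N"))$n), 0L)
  expect_equal(sum(count_transitions(rep("WAKE", 50))$n), 0L)
})

test_that("bout and transition counters agree with brute-force scanners", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      n <- sample(1:500, 1)
      labels <- random_labels(n)
      b <- detect_bouts(labels)
      bb <- brute_bouts(labels)
      expect_equal(nrow(b), nrow(bb))
      expect_equal(as.character(b$state), bb$state)
      expect_equal(b$length_epochs, bb$length_epochs)
      expect_equal(b$start_epoch, bb$start_epoch)

      tc <- count_transitions(labels)
      bt <- brute_transitions(labels)
      agg <- dplyr::count(dplyr::group_by(bt, from, to), name = "n_expected")
      merged <- dplyr::summarise(dplyr::group_by(tc, from, to), n = sum(n),
                                 .groups = "drop")
      for (r in seq_len(nrow(agg))) {
        expect_equal(
          merged$n[merged$from == agg$from[r] & merged$to == agg$to[r]],
          agg$n_expected[r]
        )
      }
      expect_equal(sum(tc$n), nrow(bt))
    }
  })
})

test_that("transition counts never exceed destination-state bout counts", {
  withr::with_seed(17, {
    for (i in 1:50) {
      labels <- random_labels(sample(10:400, 1))
      b <- detect_bouts(labels)
      tc <- count_transitions(labels)
      for (s in vigilance_states()) {
        expect_lte(sum(tc$n[tc$to == s]), sum(b$state == s))
      }
    }
  })
})

test_that("merging two same-state bouts by relabeling never raises the bout count", {
  withr::with_seed(23, {
    for (i in 1:50) {
      labels <- random_labels(sample(3:100, 1))
      n0 <- nrow(detect_bouts(labels))
      # Relabel one interposed single epoch to its neighbors' shared state.
      cand <- which(vapply(2:(length(labels) - 1), function(j) {
        labels[j - 1] == labels[j + 1] && labels[j] != labels[j - 1]
      }, logical(1))) + 1L
      if (length(cand) > 0) {
        j <- cand[1]
        merged <- labels
        merged[j] <- labels[j - 1]
        expect_lte(nrow(detect_bouts(merged)), n0)
      }
    }
  })
})

test_that("transitions are attributed to the phase of their first epoch", {
  # NREM run starting at epoch 4319 (ZT 11.997, light), wake resuming in dark.
  labels <- c(rep("WAKE", 4319), rep("NREM", 4), rep("WAKE", 10))
  h <- tibble::tibble(
    epoch = seq_along(labels) - 1L,
    zt = somnoscore:::zt_of_epoch(seq_along(labels) - 1L, 0),
    state = factor(labels, levels = vigilance_states())
  )
  tc <- count_transitions(h)
  expect_equal(sum(tc$n[tc$phase == "light" & tc$from == "WAKE" & tc$to == "NREM"]), 1L)
  expect_equal(sum(tc$n[tc$phase == "dark" & tc$from == "NREM" & tc$to == "WAKE"]), 1L)
})

test_that("onset latency finds the first two-epoch run after phase start", {
  # NREM run of 2 beginning 114 epochs after ZT 0 -> 19.0 min.
  labels <- c(rep("WAKE", 114), rep("NREM", 2), rep("WAKE", 100))
  expect_equal(onset_latency(labels, "NREM", 0), 19.0)

  # A qualifying run at phase start has zero latency.
  expect_equal(onset_latency(c("NREM", "NREM", "WAKE"), "NREM", 0), 0)

  # Isolated single epochs never qualify.
  lone <- c("WAKE", "REM", "WAKE", "WAKE", "REM", "WAKE")
  expect_message(res <- onset_latency(lone, "REM", 0), "missing")
  expect_true(is.na(res))

  expect_error(onset_latency(rep("WAKE", 10), "NREM", 12),
               class = "somnoscore_validation_error")
})

test_that("binned durations conserve time and attribute bouts to starting bins", {
  all_rem <- rep("REM", 360)
  b <- bin_durations(all_rem, 1)
  expect_equal(b$minutes[b$state == "REM"], 60)
  expect_equal(sum(b$minutes), 60)

  mixed <- c(rep("WAKE", 180), rep("NREM", 120), rep("REM", 60))
  b2 <- bin_durations(mixed, 1)
  expect_equal(b2$minutes, c(30, 20, 10))
  expect_equal(b2$bout_count, c(1L, 1L, 1L))
  expect_equal(b2$mean_bout_s, c(1800, 1200, 600))

  # Straddling bout: counted once, full length, in its starting bin.
  strad <- c(rep("WAKE", 300), rep("NREM", 120), rep("WAKE", 300))
  b3 <- bin_durations(strad, 1) # NREM run spans the hour boundary at epoch 360
  expect_warning(bin_durations(c(strad, "WAKE"), 1), "partial")
  expect_equal(b3$bout_count[b3$bin == 0 & b3$state == "NREM"], 1L)
  expect_equal(b3$bout_count[b3$bin == 1 & b3$state == "NREM"], 0L)
  expect_equal(b3$mean_bout_s[b3$bin == 0 & b3$state == "NREM"], 1200)
  # ... but the minutes stay in the bins where the epochs lie.
  expect_equal(b3$minutes[b3$bin == 0 & b3$state == "NREM"], 10)
  expect_equal(b3$minutes[b3$bin == 1 & b3$state == "NREM"], 10)

  expect_error(bin_durations(mixed, 2), class = "somnoscore_validation_error")
})

test_that("per-bin durations always sum to the bin length on simulated data", {
  h <- simulate_hypnogram(duration_h = 12, seed = 31)
  for (bh in c(1, 6)) {
    b <- bin_durations(h, bh)
    tot <- dplyr::summarise(dplyr::group_by(b, bin), m = sum(minutes))
    expect_true(all(abs(tot$m - bh * 60) < 1e-9))
  }
  # Total bouts across states equals the number of runs.
  b6 <- bin_durations(h, 6)
  expect_equal(sum(b6$bout_count), nrow(detect_bouts(h)))
})

test_that("percent and absolute change follow their closed forms", {
  v <- bin_durations(c(rep("NREM", 360), rep("WAKE", 360)), 1)
  t_ <- bin_durations(c(rep("NREM", 355), rep("WAKE", 365)), 1)
  pc <- percent_change(t_, v)
  # Vehicle 60 min NREM in bin 0; treated 59.166... -> -1.389%.
  expect_equal(pc$percent_change[pc$bin == 0 & pc$state == "NREM"],
               100 * (355 - 360) / 360, tolerance = 1e-9)
  # 71 vs 60 min is +18.33%.
  expect_equal(100 * (71 - 60) / 60, 18.33, tolerance = 1e-3)
  # Identical inputs give exactly zero everywhere.
  pc0 <- percent_change(v, v)
  expect_true(all(pc0$percent_change[!pc0$undefined] == 0))
  # Zero vehicle cells are flagged undefined, not infinite.
  expect_true(all(pc$undefined[pc$vehicle == 0]))
  expect_true(all(is.na(pc$percent_change[pc$undefined])))
  expect_false(any(is.infinite(pc$percent_change), na.rm = TRUE))

  ac <- absolute_change(t_, v)
  expect_equal(ac$absolute_change[ac$bin == 0 & ac$state == "NREM"],
               (355 - 360) * 10 / 60)
  # Anti-symmetry under argument swap.
  ac_swap <- absolute_change(v, t_)
  expect_equal(ac$absolute_change, -ac_swap$absolute_change)
  expect_true(all(absolute_change(v, v)$absolute_change == 0))

  # Mismatched bins are an error.
  v6 <- bin_durations(c(rep("NREM", 2160)), 6)
  expect_error(percent_change(v6, v), class = "somnoscore_validation_error")
})

test_that("architecture_summary bundles bins, onsets and transitions", {
  h <- simulate_hypnogram(duration_h = 24, seed = 41)
  a <- architecture_summary(h)
  expect_named(a, c("bins_1h", "bins_6h", "onsets", "transitions"))
  expect_equal(nrow(a$bins_1h), 24 * 3)
  expect_equal(nrow(a$bins_6h), 4 * 3)
  expect_equal(nrow(a$onsets), 4)
  expect_true(all(a$onsets$onset_min >= 0, na.rm = TRUE))
})
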