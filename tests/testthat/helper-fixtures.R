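# Shared fixtures and independent oracles, all built in code at test time.

# Hypnogram tibble from a compact string like "WWNNNRRW".
str_hyp <- function(s, start_zt = 0) {
  map <- c(W = "WAKE", N = "NREM", R = "REM")
  states <- map[strsplit(s, "")[[1]]]
  tibble::tibble(
    epoch = seq_along(states) - 1L,
    zt = (start_zt + (seq_along(states) - 1L) * 10 / 3600) %% 24,
    state = factor(unname(states), levels = vigilance_states())
  )
}

# Uniform random label sequence for property tests.
random_labels <- function(n) {
  sample(vigilance_states(), n, replace = TRUE)
}

# --- Independent brute-force scanners (plain epoch-by-epoch loops; no rle,
# --- no shared code with the implementation) ---------------------------------

brute_bouts <- function(states) {
  states <- as.character(states)
  out <- list()
  i <- 1L
  while (i <= length(states)) {
    j <- i
    while (j < length(states) && states[j + 1L] == states[i]) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(
      state = states[i], start_epoch = i - 1L, length_epochs = j - i + 1L
    )
    i <- j + 1L
  }
  do.call(rbind, out)
}

# Transition rule applied literally: walk forward; when >= 2 consecutive
# epochs carry a state different from the currently scored state, score one
# transition and adopt that state.
brute_transitions <- function(states) {
  states <- as.character(states)
  n <- length(states)
  res <- data.frame(from = character(0), to = character(0), at_epoch = integer(0))
  current <- states[1]
  i <- 2L
  while (i <= n) {
    if (states[i] != current && i < n && states[i + 1L] == states[i]) {
      res <- rbind(res, data.frame(from = current, to = states[i], at_epoch = i - 1L))
      current <- states[i]
      # jump past this run
      while (i < n && states[i + 1L] == states[i]) i <- i + 1L
    }
    i <- i + 1L
  }
  res
}

# One small labeled recording reused by several test files (built once per
# test run; 30 min keeps featurization instant).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_recording(duration_h = 0.5, seed = 42)
    cache
  }
})

# Synthetic 210-feature window tibble with three well-separated Gaussian
# class clusters (for classifier unit tests).
toy_windows <- function(n_per_class = 60, sep = 5, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(vigilance_states(), each = n_per_class)
    x <- do.call(rbind, lapply(0:2, function(k) {
      matrix(rnorm(n_per_class * 210, mean = k * sep, sd = sd), n_per_class)
    }))
    colnames(x) <- sprintf("f%03d", 1:210)
    dplyr::bind_cols(
      tibble::tibble(
        center_epoch = seq_along(lab) - 1L,
        label = factor(lab, levels = vigilance_states())
      ),
      tibble::as_tibble(x)
    )
  })
}
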