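test_that("stratified split hits the 64/16/20 sizes exactly", {
  w <- toy_windows(n_per_class = 100) # 300 samples
  s <- split_windows(w, seed = 1)
  expect_equal(as.numeric(table(s$split)), c(192, 48, 60))

  # 1000 samples across unequal classes still split 640/160/200 overall.
  w2 <- toy_windows(n_per_class = 400, seed = 2)[c(1:500, 401:700, 801:1000), ]
  expect_equal(nrow(w2), 1000L)
  s2 <- split_windows(w2, seed = 3)
  expect_equal(as.numeric(table(s2$split)), c(640, 160, 200))
  # Stratified: every class present in every split, proportions preserved
  # (class counts are 400/400/200 here).
  tab <- table(s2$label, s2$split)
  expect_true(all(tab > 0))
  expect_equal(as.numeric(tab[, "test"]), c(80, 80, 40))
})

test_that("tiny splits round with the remainder going to training", {
  w <- toy_windows(n_per_class = 60)[c(1, 2, 61, 62, 121), ]
  s <- split_windows(w, seed = 1)
  expect_equal(as.numeric(table(s$split)), c(3, 1, 1))
})

test_that("splitting is deterministic in the seed and exhaustive", {
  w <- toy_windows(n_per_class = 50)
  a <- split_windows(w, seed = 7)
  b <- split_windows(w, seed = 7)
  expect_identical(a$split, b$split)
  expect_false(identical(a$split, split_windows(w, seed = 8)$split))
  expect_false(anyNA(a$split))
})

test_that("oversampling balances training classes to the majority count", {
  w <- toy_windows(n_per_class = 300, seed = 4)
  train <- w[c(1:250, 301:350, 601:625), ] # 250 / 50 / 25
  os <- oversample_training(train, seed = 1)
  expect_equal(as.numeric(table(os$label)), c(250, 250, 250))
  # Original rows are all retained.
  expect_true(all(train$center_epoch %in% os$center_epoch))

  balanced <- w[c(1:30, 301:330, 601:630), ]
  os2 <- oversample_training(balanced, seed = 1)
  expect_equal(nrow(os2), nrow(balanced))

  expect_error(oversample_training(w[1:10, ], seed = 1),
               class = "somnoscore_validation_error")
})

test_that("the MLP separates well-separated clusters perfectly", {
  w <- toy_windows(n_per_class = 80, sep = 5, sd = 0.5, seed = 5)
  s <- split_windows(w, seed = 5)
  # The training split is smaller than one default minibatch, so allow
  # enough passes (= gradient steps here) for Adam to converge.
  cfg <- mlp_config(hidden_size = 32, max_iterations = 150, patience = 150,
                    learning_rate = 0.01, seed = 5)
  m <- fit_vigilance_mlp(s[s$split == "train", ], s[s$split == "validation", ], cfg)
  ev <- evaluate_classifier(m, s[s$split == "test", ])
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$macro_f1, 1.0)

  # Independent cross-check: an off-the-shelf single-hidden-layer net also
  # finds this separable problem trivial.
  skip_if_not_installed("nnet")
  tr <- s[s$split == "train", ]
  xs <- scale(somnoscore:::window_matrix(tr))
  fit <- nnet::nnet(xs, nnet::class.ind(tr$label),
                    size = 4, softmax = TRUE, trace = FALSE, maxit = 200)
  xt <- scale(somnoscore:::window_matrix(s[s$split == "test", ]),
              center = attr(xs, "scaled:center"), scale = attr(xs, "scaled:scale"))
  pred <- factor(colnames(fit$fitted.values)[max.col(predict(fit, xt))],
                 levels = vigilance_states())
  expect_equal(mean(pred == s$label[s$split == "test"]), 1.0)
})

test_that("training on shuffled labels scores at chance on balanced data", {
  withr::with_seed(11, {
    n <- 3000
    x <- matrix(rnorm(n * 210), n, 210, dimnames = list(NULL, sprintf("f%03d", 1:210)))
    w <- dplyr::bind_cols(
      tibble::tibble(center_epoch = seq_len(n) - 1L,
                     label = factor(rep(vigilance_states(), length.out = n),
                                    levels = vigilance_states())),
      tibble::as_tibble(x)
    )
  })
  s <- split_windows(w, seed = 11)
  cfg <- mlp_config(hidden_size = 32, max_iterations = 5, patience = 5, seed = 11)
  m <- fit_vigilance_mlp(s[s$split == "train", ], s[s$split == "validation", ], cfg)
  ev <- evaluate_classifier(m, s[s$split == "test", ])
  expect_lt(abs(ev$accuracy - 1 / 3), 0.05)
})

test_that("training is deterministic: same data and seed give identical weights", {
  w <- toy_windows(n_per_class = 40, seed = 6)
  s <- split_windows(w, seed = 6)
  cfg <- mlp_config(hidden_size = 16, max_iterations = 3, seed = 6)
  m1 <- fit_vigilance_mlp(s[s$split == "train", ], s[s$split == "validation", ], cfg)
  m2 <- fit_vigilance_mlp(s[s$split == "train", ], s[s$split == "validation", ], cfg)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
  expect_identical(m1$history, m2$history)
})

test_that("prediction takes the softmax argmax with ties to the lowest index", {
  w <- toy_windows(n_per_class = 40, seed = 6)
  s <- split_windows(w, seed = 6)
  cfg <- mlp_config(hidden_size = 16, max_iterations = 5, seed = 6)
  m <- fit_vigilance_mlp(s[s$split == "train", ], s[s$split == "validation", ], cfg)
  p <- predict(m, w, type = "prob")
  expect_equal(dim(p), c(nrow(w), 3L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  cls <- predict(m, w)
  expect_identical(as.character(cls),
                   vigilance_states()[max.col(as.matrix(p), ties.method = "first")])
  # Feature-length mismatch is rejected.
  expect_error(predict(m, w[, 1:100]), class = "somnoscore_validation_error")
})

test_that("per-epoch scoring assigns center-window labels with edge inheritance", {
  h <- str_hyp(strrep("W", 60))
  rec <- synthesize_signals(h, seed = 13)
  f <- featurize_recording(rec, h)
  # Train quickly on mixed-state data so the model knows all classes.
  sim <- shared_sim()
  ftr <- featurize_recording(sim$recording, sim$hypnogram)
  s <- split_windows(build_windows(ftr), seed = 13)
  m <- fit_vigilance_mlp(oversample_training(s[s$split == "train", ], 13),
                         s[s$split == "validation", ],
                         mlp_config(hidden_size = 64, max_iterations = 10, seed = 13))
  hyp <- predict_hypnogram(m, f)
  expect_equal(nrow(hyp), 60L)
  expect_true(all(hyp$state == "WAKE"))
  # Edge epochs copy the nearest window's label by construction.
  w <- build_windows(f)
  pred_w <- predict(m, w)
  expect_identical(as.character(hyp$state[1:2]), rep(as.character(pred_w[1]), 2))
  expect_identical(as.character(hyp$state[59:60]),
                   rep(as.character(pred_w[length(pred_w)]), 2))
})

test_that("evaluation metrics match closed forms on hand-built predictions", {
  truth <- factor(rep(vigilance_states(), each = 30), levels = vigilance_states())
  # Perfect predictions.
  ev <- somnoscore:::confusion_evaluation(truth, truth)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$macro_f1, 1.0)
  expect_equal(diag(ev$confusion), c(WAKE = 30L, NREM = 30L, REM = 30L))
  expect_equal(sum(ev$confusion) - sum(diag(ev$confusion)), 0L)

  # Everything predicted WAKE: accuracy 1/3; F1(WAKE) = 2*(1/3)*1/(4/3) = 0.5.
  all_wake <- factor(rep("WAKE", 90), levels = vigilance_states())
  ev2 <- somnoscore:::confusion_evaluation(truth, all_wake)
  expect_equal(ev2$accuracy, 1 / 3)
  expect_equal(unname(ev2$f1), c(0.5, 0, 0))
  expect_equal(unname(rowSums(ev2$confusion)), c(30, 30, 30))

  expect_error(evaluate_classifier(structure(list(), class = "vigilance_mlp"),
                                   toy_windows()[0, ]),
               class = "somnoscore_validation_error")
})

test_that("tidy and glance methods summarize models and evaluations", {
  w <- toy_windows(n_per_class = 40, seed = 3)
  s <- split_windows(w, seed = 3)
  cfg <- mlp_config(hidden_size = 8, max_iterations = 4, seed = 3)
  m <- fit_vigilance_mlp(s[s$split == "train", ], s[s$split == "validation", ], cfg)
  expect_named(tidy(m), c("pass", "train_loss", "validation_loss"))
  g <- glance(m)
  expect_equal(g$hidden_size, 8)
  ev <- evaluate_classifier(m, s[s$split == "test", ])
  td <- tidy(ev)
  expect_equal(nrow(td), 3L)
  expect_equal(glance(ev)$accuracy, ev$accuracy)
})
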