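test_that("IHR follows the closed form 60/RR on a 1-Hz hold grid", {
  s <- ihr(c(0, 1, 2, 3), duration_s = 4)
  expect_true(all(s$samples == 60))
  expect_equal(s$rate_hz, 1)
  s2 <- ihr(seq(0, 3, by = 0.5), duration_s = 3)
  expect_true(all(s2$samples == 120))
  s3 <- ihr(c(0, 0.8, 1.7))
  expect_equal(attr(s3, "ihr_bpm"), c(60 / 0.8, 60 / 0.9), tolerance = 1e-12)
  expect_error(ihr(c(1, 1, 2)), "increasing")
  expect_error(ihr(3), "2 R peaks")
})

test_that("R-peak detection recovers a synthetic impulse train", {
  fs <- 500
  dur <- 120
  set.seed(8)
  truth <- cumsum(c(0.5, rnorm(118, 1, 0.03)))
  truth <- truth[truth < dur - 0.5]
  n <- dur * fs
  x <- rnorm(n, 0, 0.02)
  qrs_half <- as.integer(0.03 * fs)
  qrs <- exp(-((seq(-qrs_half, qrs_half)) / (0.012 * fs))^2)
  for (rp in truth) {
    c0 <- as.integer(round(rp * fs)) + 1L
    idx <- (c0 - qrs_half):(c0 + qrs_half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + qrs[ok]
  }
  det <- detect_r_peaks(signal_stream(x, fs, 0, "ecg"))
  match_tol <- 0.05
  hits <- vapply(truth, function(tp) any(abs(det - tp) <= match_tol), TRUE)
  prec <- vapply(det, function(dp) any(abs(truth - dp) <= match_tol), TRUE)
  expect_gte(mean(hits), 0.99)
  expect_gte(mean(prec), 0.99)
})

test_that("alternating RR intervals are recovered within 20 ms", {
  fs <- 500
  rr <- rep(c(0.8, 1.0), 40)
  truth <- cumsum(c(0.5, rr))
  dur <- ceiling(max(truth)) + 1
  n <- dur * fs
  x <- rnorm(n, 0, 0.01)
  qrs_half <- as.integer(0.03 * fs)
  qrs <- exp(-((seq(-qrs_half, qrs_half)) / (0.012 * fs))^2)
  for (rp in truth) {
    c0 <- as.integer(round(rp * fs)) + 1L
    x[(c0 - qrs_half):(c0 + qrs_half)] <- x[(c0 - qrs_half):(c0 + qrs_half)] + qrs
  }
  det <- detect_r_peaks(signal_stream(x, fs, 0, "ecg"))
  expect_gte(length(det), length(truth) - 2)
  rr_det <- diff(det)
  rr_truth <- diff(truth)
  m <- min(length(rr_det), length(rr_truth))
  expect_lt(max(abs(sort(rr_det)[1:m] - sort(rr_truth)[1:m])), 0.02)
  expect_warning(det0 <- detect_r_peaks(signal_stream(rep(0, 120 * fs),
                                                      fs, 0, "ecg")), "flat")
  expect_length(det0, 0)
})

test_that("the LSTM learns, is seed-deterministic and fixed-size", {
  set.seed(30)
  n <- 60; Tn <- 40
  x <- array(rnorm(n * Tn * 9), c(n, Tn, 9))
  y <- rep(c("NOR", "OSA", "CSA", "HYP"), length.out = n)
  for (k in seq_len(n)) {       # class-dependent mean shift: separable
    x[k, , match(y[k], EK)] <- x[k, , match(y[k], EK)] + 3
  }
  cfg <- event_model_config(epochs = 10, seed = 5)
  m1 <- train_event_model(list(x = x, y = y), cfg)
  m2 <- train_event_model(list(x = x, y = y), cfg)
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_identical(m1$par, m2$par)
  expect_lt(tail(m1$loss_curve, 1), m1$loss_curve[1])
  # parameter count fixed by (9, 80, 4); N changes sequence length only
  n_par <- function(m) sum(vapply(m$par, length, 0L))
  expect_equal(n_par(m1), 9 * 320 + 80 * 320 + 320 + 80 * 4 + 4)
  cfg2 <- event_model_config(epochs = 1, seq_span_s = 30, seed = 5)
  m3 <- train_event_model(list(x = array(rnorm(20 * 60 * 9), c(20, 60, 9)),
                               y = rep(c("NOR", "OSA"), 10)), cfg2)
  expect_equal(n_par(m3), n_par(m1))
  expect_error(train_event_model(list(x = x, y = rep("NOR", n)), cfg),
               "single class")
})

test_that("a small batch can be memorised outright", {
  set.seed(31)
  n <- 10; Tn <- 40
  x <- array(rnorm(n * Tn * 9), c(n, Tn, 9))
  y <- rep(c("NOR", "OSA", "CSA", "HYP"), length.out = n)
  cfg <- event_model_config(epochs = 50, batch_size = 10, seed = 6)
  m <- train_event_model(list(x = x, y = y), cfg)
  xs <- x
  for (j in 1:9) xs[, , j] <- (xs[, , j] - m$mu[j]) / m$sd[j]
  probs <- apneascreen:::lstm_forward(m$par, xs)$probs
  expect_equal(EK[apply(probs, 1, which.max)], y)
})

test_that("probability rows are softmax-normalised and feature order is enforced", {
  set.seed(32)
  frames <- data.frame(t_s = seq(60, 120, by = 0.5))
  for (nm in apneascreen:::FEATURE_NAMES) frames[[nm]] <- rnorm(nrow(frames))
  class(frames) <- c("feature_frames", "data.frame")
  x <- array(rnorm(30 * 40 * 9), c(30, 40, 9))
  y <- rep(c("NOR", "OSA"), 15)
  m <- train_event_model(list(x = x, y = y),
                         event_model_config(epochs = 2, seed = 1))
  pr <- predict_event_probs(m, frames)
  expect_equal(nrow(pr), nrow(frames))
  sums <- rowSums(as.matrix(pr[, c("p_nor", "p_osa", "p_csa", "p_hyp")]))
  expect_true(all(abs(sums - 1) < 1e-6))
  perm <- frames[, c("t_s", rev(apneascreen:::FEATURE_NAMES))]
  class(perm) <- c("feature_frames", "data.frame")
  expect_error(predict_event_probs(m, perm), "order")
})

test_that("label decisions take the argmax with the documented tie order", {
  pr <- data.frame(t_s = c(0, 0.5, 1), p_nor = c(0.1, 0.25, 0.2),
                   p_osa = c(0.7, 0.25, 0.2), p_csa = c(0.1, 0.25, 0.2),
                   p_hyp = c(0.1, 0.25, 0.4))
  expect_equal(decide_labels(pr), c("OSA", "NOR", "HYP"))
})

test_that("the sleep-wake CNN halves lengths, learns and respects the tie rule", {
  cfg <- sleepwake_config()
  L <- cfg$input_span_s
  for (b in seq_len(cfg$conv_blocks)) for (s in cfg$strides) L <- ceiling(L / s)
  expect_lte(L, 10)
  set.seed(33)
  n <- 40
  x <- array(rnorm(n * 300 * 2, 60, 1), c(n, 300, 2))
  y <- rep(c("sleep", "wake"), n / 2)
  # wake: higher-variance heart rate (the median normalization removes
  # mean shifts, so dispersion is the learnable signal)
  x[y == "wake", , 1] <- rnorm(sum(y == "wake") * 300, 80, 10)
  cfg <- sleepwake_config(epochs = 60, batch_size = 10, seed = 3)
  m1 <- train_sleepwake(list(x = x, y = y), cfg)
  m2 <- train_sleepwake(list(x = x, y = y), cfg)
  expect_identical(m1$par, m2$par)
  p <- predict_sleepwake_probs(m1, x)
  expect_gte(mean(ifelse(p[, 2] >= p[, 1], "wake", "sleep") == y), 0.9)
  expect_error(train_sleepwake(list(x = array(0, c(4, 100, 2)),
                                    y = c("sleep", "wake", "sleep", "wake")),
                               cfg), "shorter")
  expect_error(train_sleepwake(list(x = x, y = rep("sleep", n)), cfg),
               "single class")
  # equal outputs score as wake
  expect_equal(ifelse(0.5 >= 0.5, "wake", "sleep"), "wake")
})

test_that("shuffled labels collapse held-out skill to chance", {
  set.seed(34)
  n <- 120; Tn <- 40
  x <- array(rnorm(n * Tn * 9), c(n, Tn, 9))
  y <- rep(EK, length.out = n)
  for (k in seq_len(n)) x[k, , match(y[k], EK)] <- x[k, , match(y[k], EK)] + 3
  y_shuf <- sample(y)
  tr <- 1:80; te <- 81:120
  m <- train_event_model(list(x = x[tr, , ], y = y_shuf[tr]),
                         event_model_config(epochs = 15, seed = 7))
  xs <- x[te, , ]
  for (j in 1:9) xs[, , j] <- (xs[, , j] - m$mu[j]) / m$sd[j]
  pred <- EK[apply(apneascreen:::lstm_forward(m$par, xs)$probs, 1, which.max)]
  f1 <- macro_f1(pred, y[te])
  expect_lt(f1, 0.35)   # at or below chance for four balanced classes
})
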