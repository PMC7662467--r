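# Shared fixtures and independent oracles, built in code at test time.

EK <- c("NOR", "OSA", "CSA", "HYP")

make_tone <- function(freq_hz, dur_s, fs = 50, amp = 1, phase = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq_hz * t + phase)
}

# independent brute-force desaturation oracle: explicit loop over the
# difference sequence, 20-s accumulation, threshold, 20-s back-shift
oracle_desat_marks <- function(x, drop_pct = 3, win = 20) {
  n <- length(x)
  mark <- rep(FALSE, n)
  depth <- rep(0, n)
  for (i in 2:n) {
    lo <- max(1, i - win)
    acc <- 0
    if (i - win >= 1) {
      for (j in (i - win + 1):i) acc <- acc + (x[j] - x[j - 1])
    } else {
      for (j in 2:i) acc <- acc + (x[j] - x[j - 1])
    }
    if (-acc >= drop_pct) {
      dst <- i - win
      if (dst >= 1) {
        mark[dst] <- TRUE
        depth[dst] <- -acc
      }
    }
  }
  list(mark = mark, depth = depth)
}

# periodogram band-energy oracle for the frequency ratio: rectangular
# window, FFT, trapezoidal integration on the frequency grid
oracle_fr <- function(seg, fs, floor_value = -6) {
  seg <- seg - mean(seg)
  n <- length(seg)
  sp <- Mod(stats::fft(seg))^2
  nh <- floor(n / 2) + 1
  freq <- (seq_len(nh) - 1) * fs / n
  trapz <- function(f, p) sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  bsel <- function(lo, hi) {
    s <- freq >= lo & freq <= hi
    if (sum(s) < 2) return(0)
    trapz(freq[s], sp[seq_len(nh)][s])
  }
  num <- bsel(0.8, 1.5); den <- bsel(0.1, 0.8)
  if (num <= 0 || den <= 0) return(floor_value)
  max(log10(num / den), floor_value)
}

macro_f1 <- function(pred, truth, classes = EK) {
  cm <- table(factor(pred, classes), factor(truth, classes))
  f1 <- vapply(seq_along(classes), function(k) {
    p <- if (sum(cm[k, ]) > 0) cm[k, k] / sum(cm[k, ]) else 0
    s <- if (sum(cm[, k]) > 0) cm[k, k] / sum(cm[, k]) else 0
    if (p + s == 0) 0 else 2 * p * s / (p + s)
  }, 0)
  mean(f1)
}

# a small recording for io tests (deterministic)
small_sim <- function(seed = 7, duration_h = 0.1) {
  generate_recording(sim_config(
    duration_h = duration_h, seed = seed,
    event_rate_per_h = c(OSA = 10, CSA = 0, HYP = 10),
    wake_bouts = list(count = 0, len_range_s = c(60, 90))))
}

# shared slot for artifacts reused across test files (filled by the
# end-to-end acceptance block, reused by the invariants block)
.shared <- new.env(parent = emptyenv())

# trained model pair for plumbing tests: reuse the acceptance run's models
# when available, otherwise train a small pair once and cache it
get_pipeline_models <- function() {
  if (!is.null(.shared$models)) return(.shared$models)
  ev_cfg <- event_model_config(epochs = 12, seed = 99)
  sw_cfg <- sleepwake_config(epochs = 40, seed = 99)
  ts <- make_training_set(
    sim_config(wake_bouts = list(count = 2, len_range_s = c(120, 300))),
    n_nights = 2, seed = 9900, event_cfg = ev_cfg, sw_cfg = sw_cfg)
  ev <- train_event_model(list(x = ts$event$x, y = ts$event$y), ev_cfg)
  sw <- train_sleepwake(list(x = ts$sleepwake$x, y = ts$sleepwake$y), sw_cfg)
  .shared$models <- list(event_model = ev, sleepwake_model = sw)
  .shared$models
}
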