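test_that("the generator is seed-deterministic sample for sample", {
  a <- generate_recording(sim_config(duration_h = 0.1, seed = 12))
  b <- generate_recording(sim_config(duration_h = 0.1, seed = 12))
  expect_identical(a$recording$tho_taa$x$samples, b$recording$tho_taa$x$samples)
  expect_identical(a$recording$spo2$samples, b$recording$spo2$samples)
  expect_identical(a$recording$ecg$samples, b$recording$ecg$samples)
  expect_identical(a$recording$r_peaks, b$recording$r_peaks)
  expect_identical(events_to_df(a$recording$events),
                   events_to_df(b$recording$events))
  d <- generate_recording(sim_config(duration_h = 0.1, seed = 13))
  expect_false(identical(a$recording$tho_taa$x$samples,
                         d$recording$tho_taa$x$samples))
})

test_that("scripted truth AHI equals compute_ahi on truth annotations", {
  # 25 events over one hour of uninterrupted sleep -> AHI exactly 25
  cfg <- sim_config(duration_h = 1, seed = 21,
                    event_rate_per_h = c(OSA = 11, CSA = 6, HYP = 8),
                    wake_bouts = list(count = 0, len_range_s = c(60, 60)))
  sim <- generate_recording(cfg)
  expect_equal(sim$truth$ahi, 25)
  expect_length(sim$recording$events, 25)
  re <- compute_ahi(sim$recording$events, sim$recording$hypnogram)
  expect_equal(re$ahi, sim$truth$ahi)
  expect_equal(re$counts, sim$truth$counts)
  # events stay clear of wake and never overlap
  df <- events_to_df(sim$recording$events)
  expect_true(all(df$start_s[-1] >= df$end_s[-nrow(df)]))
  expect_true(all(df$end_s - df$start_s >= 10))
})

test_that("a zero-event night has no detectable desaturation", {
  cfg <- sim_config(duration_h = 0.5, seed = 22,
                    event_rate_per_h = c(OSA = 0, CSA = 0, HYP = 0))
  sim <- generate_recording(cfg)
  expect_equal(sim$truth$ahi, 0)
  expect_length(sim$recording$events, 0)
  dm <- detect_desaturation(sim$recording$spo2)
  expect_equal(nrow(dm$runs), 0)
})

test_that("every scripted desaturation is recovered exactly", {
  for (seed in 101:106) {
    sim <- generate_recording(sim_config(seed = seed))
    dm <- detect_desaturation(sim$recording$spo2)
    expect_equal(nrow(dm$runs), nrow(attr(sim$recording, "truth_desat")))
  }
})

test_that("hypopnea segments show the scripted 30% envelope reduction", {
  cfg <- sim_config(duration_h = 0.5, seed = 23,
                    event_rate_per_h = c(OSA = 0, CSA = 0, HYP = 8),
                    posture_change_rate_per_h = 0,
                    wake_bouts = list(count = 0, len_range_s = c(60, 60)))
  sim <- generate_recording(cfg)
  sel <- select_axis(sim$recording$tho_taa)
  amp <- instantaneous_amplitude(sel$effort)
  tt <- stream_times(amp)
  ratios <- vapply(sim$recording$events, function(ev) {
    inside <- tt >= ev$start_s + 4 & tt <= ev$end_s - 4
    before <- tt >= ev$start_s - 30 & tt <= ev$start_s - 10
    median(amp$samples[inside]) / median(amp$samples[before])
  }, 0)
  expect_lt(abs(median(ratios) - 0.7), 0.05)
})

test_that("effort paradox: thoracic and abdominal envelopes modulate in antiphase during OSA", {
  cfg <- sim_config(duration_h = 0.5, seed = 24,
                    event_rate_per_h = c(OSA = 10, CSA = 0, HYP = 0),
                    posture_change_rate_per_h = 0,
                    wake_bouts = list(count = 0, len_range_s = c(60, 60)))
  sim <- generate_recording(cfg)
  tho <- instantaneous_amplitude(select_axis(sim$recording$tho_taa)$effort)
  abd <- instantaneous_amplitude(select_axis(sim$recording$abd_taa)$effort)
  tt <- stream_times(tho)
  n_anti <- 0
  detrend <- function(v) residuals(lm(v ~ seq_along(v)))
  for (ev in sim$recording$events) {
    inside <- tt >= ev$start_s + 2 & tt <= ev$end_s - 2
    a <- detrend(tho$samples[inside])
    b <- detrend(abd$samples[inside])
    # antiphase envelope modulation (the 14-s alternation) -> negative
    # correlation of the detrended envelopes, i.e. a phase difference
    # beyond 90 degrees
    if (cor(a, b) < 0) n_anti <- n_anti + 1
  }
  # property holds for the clear majority of events (short events near the
  # envelope-estimator settling time can blur the modulation)
  expect_gte(n_anti, ceiling(0.75 * length(sim$recording$events)))
})

test_that("CSA segments depress AR and raise FR relative to normal breathing", {
  cfg <- sim_config(duration_h = 0.5, seed = 25,
                    event_rate_per_h = c(OSA = 0, CSA = 8, HYP = 0),
                    posture_change_rate_per_h = 0,
                    wake_bouts = list(count = 0, len_range_s = c(60, 60)))
  sim <- generate_recording(cfg)
  pf <- pipeline_features(sim$recording)
  lab <- apneascreen:::frame_truth_labels(pf$frames, sim$recording$events)
  csa <- lab == "CSA"; nor <- lab == "NOR"
  expect_lt(median(pf$frames$ar_tho[csa]), 0.3)
  expect_gt(median(pf$frames$fr_tho[csa]), median(pf$frames$fr_tho[nor]))
})

test_that("training sets are night-disjoint with the configured class mix", {
  ts <- make_training_set(sim_config(duration_h = 0.25, seed = 1),
                          n_nights = 4, seed = 400)
  expect_equal(sort(unique(ts$event$night)), 1:4)
  expect_length(intersect(ts$split$train, ts$split$test), 0)
  expect_true(all(ts$event$night[ts$event$night %in% ts$split$test] %in%
                    ts$split$test))
  expect_setequal(unique(ts$sleepwake$y), c("sleep", "wake"))
  expect_equal(dim(ts$event$x)[2:3], c(40, 9))
  expect_equal(dim(ts$sleepwake$x)[2:3], c(300, 2))
})

test_that("an impossible event load is refused", {
  cfg <- sim_config(duration_h = 0.2, seed = 26,
                    event_rate_per_h = c(OSA = 200, CSA = 100, HYP = 100))
  expect_error(generate_recording(cfg), "event load")
})
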