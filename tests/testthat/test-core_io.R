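test_that("domain types enforce their invariants", {
  expect_error(signal_stream(numeric(0), 50), "length")
  expect_error(signal_stream(1:10, -1))
  expect_error(signal_stream(1:10, 50, label = "bogus"), "label")
  expect_error(event_interval(10, 15, "OSA"), "10 s")   # apneic < 10 s
  expect_s3_class(event_interval(10, 20, "OSA"), "event_interval")
  expect_equal(event_interval(0, 30, "MIXED")$kind, "OSA")
  expect_error(hypno_epoch(17, "sleep"))
  s <- signal_stream(rep(0, 100), 50)
  expect_error(triaxial_stream(s, s, signal_stream(rep(0, 50), 50), "thoracic"),
               "share")
  expect_error(recording(triaxial_stream(s, s, s, "thoracic"),
                         triaxial_stream(s, s, s, "abdominal"),
                         signal_stream(rep(97, 2), 1),
                         r_peaks = c(1, 1)), "increasing")
})

test_that("SpO2 cleaning interpolates dropouts linearly without changing length", {
  x <- rep(96, 60)
  x[20:24] <- 0                      # 5-s dropout
  x[40] <- 120                       # out-of-range spike
  cl <- clean_spo2(signal_stream(x, 1, 0, "spo2"))
  expect_length(cl$samples, 60)
  # oracle: straight line between the valid neighbours
  expect_equal(cl$samples[20:24], rep(96, 5))
  expect_equal(cl$samples[40], 96)
  x2 <- c(rep(90, 10), rep(0, 5), rep(94, 10))
  cl2 <- clean_spo2(signal_stream(x2, 1, 0, "spo2"))
  expect_equal(cl2$samples[11:15],
               approx(c(10, 16), c(90, 94), xout = 11:15)$y)
  expect_true(all(cl2$samples >= 50 & cl2$samples <= 100))
})

test_that("CSV round trip reproduces a simulated recording", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  files <- write_recording_csv(sim$recording, dir, prefix = "truth_")
  rec2 <- read_recording(list(taa = files$taa, spo2 = files$spo2,
                              ecg = files$ecg, r_peaks = files$r_peaks,
                              events = files$events,
                              hypnogram = files$hypnogram),
                         format = "csv")
  expect_equal(rec2$tho_taa$x$samples, sim$recording$tho_taa$x$samples,
               tolerance = 1e-9)
  expect_equal(rec2$abd_taa$z$samples, sim$recording$abd_taa$z$samples,
               tolerance = 1e-9)
  expect_equal(rec2$spo2$samples, sim$recording$spo2$samples,
               tolerance = 1e-9)
  expect_equal(rec2$r_peaks, sim$recording$r_peaks, tolerance = 1e-9)
  expect_equal(events_to_df(rec2$events), events_to_df(sim$recording$events),
               tolerance = 1e-9)
  expect_equal(hypnogram_states(rec2$hypnogram) == "sleep",
               hypnogram_states(sim$recording$hypnogram) == "sleep")
})

test_that("EDF twin of the CSV bundle yields the same recording", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  edf_path <- file.path(dir, "rec.edf")
  write_recording_edf(sim$recording, edf_path)
  rec2 <- read_recording(list(edf = edf_path), format = "edf")
  # EDF stores 16-bit samples: agreement to within one quantization step
  for (ax in c("x", "y", "z")) {
    orig <- sim$recording$tho_taa[[ax]]$samples
    got <- rec2$tho_taa[[ax]]$samples
    q <- diff(range(orig)) / 65535
    expect_lt(max(abs(got - orig)), 1.5 * q)
  }
  expect_equal(rec2$spo2$rate_hz, 1)
  expect_lt(max(abs(rec2$spo2$samples - sim$recording$spo2$samples)), 0.01)
})

test_that("missing mandatory channels fail with the role named", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(spo2 = rep(97, 120)), file.path(dir, "spo2.csv"),
            row.names = FALSE)
  expect_error(read_recording(list(spo2 = file.path(dir, "spo2.csv")),
                              format = "csv"), "taa")
  write.csv(data.frame(bad = 1:10), file.path(dir, "taa.csv"), row.names = FALSE)
  expect_error(read_recording(list(taa = file.path(dir, "taa.csv"),
                                   spo2 = file.path(dir, "spo2.csv")),
                              format = "csv"), "tho_x")
  expect_error(read_recording(list(taa = file.path(dir, "nope.csv"),
                                   spo2 = file.path(dir, "spo2.csv"))),
               "not found")
})

test_that("AHI report JSON round-trips and encodes the zero/30-event cases", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rep.json")
  r0 <- ahi_report(list(), tst_h = 6)
  write_report(r0, p)
  r0b <- read_report(p)
  expect_equal(r0b$ahi, 0)
  expect_equal(r0b$severity, "normal")
  evs <- lapply(seq_len(30), function(i)
    event_interval(100 * i, 100 * i + 20, "OSA"))
  r1 <- ahi_report(evs, tst_h = 6)
  write_report(r1, p)
  expect_equal(jsonlite::read_json(p)$ahi, 5.0)
  r1b <- read_report(p)
  expect_equal(r1b$ahi, r1$ahi, tolerance = 1e-12)
  expect_equal(r1b$counts, r1$counts)
  expect_equal(events_to_df(r1b$events), events_to_df(r1$events),
               tolerance = 1e-9)
})

test_that("a simulator-scored truth report survives serialization", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "truth.json")
  write_report(sim$truth, p)
  back <- read_report(p)
  expect_equal(back$ahi, sim$truth$ahi, tolerance = 1e-9)
  expect_equal(back$severity, sim$truth$severity)
  expect_equal(back$tst_h, sim$truth$tst_h, tolerance = 1e-9)
})
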