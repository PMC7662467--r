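test_that("desaturation detection equals the brute-force oracle exactly", {
  set.seed(50)
  for (trial in 1:1000) {
    n <- sample(60:180, 1)
    x <- 97 + cumsum(rnorm(n, 0, 0.4))
    x <- pmin(100, pmax(70, x))
    dm <- detect_desaturation(signal_stream(x, 1, 0, "spo2"))
    or <- oracle_desat_marks(x)
    expect_identical(dm$mark, or$mark)
    expect_equal(dm$depth, or$depth, tolerance = 1e-12)
  }
})

test_that("hand-built desaturation cases behave as scored", {
  const <- detect_desaturation(signal_stream(rep(97, 300), 1, 0, "spo2"))
  expect_equal(nrow(const$runs), 0)

  # 4% ramp over 10 s starting at t = 100
  x <- rep(97, 300)
  tt <- 0:299
  x[tt >= 100 & tt < 110] <- 97 - 0.4 * (tt[tt >= 100 & tt < 110] - 100)
  x[tt >= 110] <- 93
  dm <- detect_desaturation(signal_stream(x, 1, 0, "spo2"))
  expect_equal(nrow(dm$runs), 1)
  or <- oracle_desat_marks(x)
  expect_identical(dm$mark, or$mark)
  # onset frozen from the oracle: the accumulated drop first reaches 3%
  # at t = 108, so the 20-s-compensated mark begins at t = 88
  expect_equal(dm$runs$start_s[1], 88)
  expect_equal(dm$runs$max_drop_pct[1], 4, tolerance = 1e-9)

  # a 2% dip never reaches the 3% criterion
  x2 <- rep(97, 300)
  x2[tt >= 100 & tt < 110] <- 97 - 0.2 * (tt[tt >= 100 & tt < 110] - 100)
  x2[tt >= 110 & tt < 140] <- 95
  x2[tt >= 140] <- 97
  dm2 <- detect_desaturation(signal_stream(x2, 1, 0, "spo2"))
  expect_equal(nrow(dm2$runs), 0)
})

test_that("fusion applies the desaturation rescue and the wake veto", {
  mk_probs <- function(labels) {
    p <- matrix(0.05, length(labels), 4)
    p[cbind(seq_along(labels), match(labels, EK))] <- 0.85
    out <- data.frame(t_s = seq(0, by = 0.5, length.out = length(labels)),
                      p_nor = p[, 1], p_osa = p[, 2], p_csa = p[, 3],
                      p_hyp = p[, 4])
    class(out) <- c("prob_series", "data.frame")
    out
  }
  desat <- structure(list(runs = data.frame(start_s = 10, end_s = 30,
                                            max_drop_pct = 4)),
                     class = "desat_marks")
  # NOR argmax inside an unexplained desaturation run -> HYP
  probs <- mk_probs(rep("NOR", 120))
  lab <- fuse(probs, desat, NULL)
  expect_true(all(lab[probs$t_s >= 10 & probs$t_s < 30] == "HYP"))
  expect_true(all(lab[probs$t_s >= 30] == "NOR"))
  # OSA argmax inside a desaturation run is kept
  probs2 <- mk_probs(rep(c("NOR", "OSA"), times = c(20, 100)))
  lab2 <- fuse(probs2, desat, NULL)
  expect_true(all(lab2[probs2$t_s >= 10 & probs2$t_s < 30] == "OSA"))
  # non-NOR labels inside wake epochs are reset
  probs3 <- mk_probs(rep("OSA", 120))
  hypno <- hypnogram_from_states(c("wake", "sleep"))
  lab3 <- fuse(probs3, NULL, hypno)
  expect_true(all(lab3[probs3$t_s < 30] == "NOR"))
  expect_true(all(lab3[probs3$t_s >= 30] == "OSA"))
  probs_bad <- mk_probs(rep("NOR", 400))
  expect_error(fuse(probs_bad, NULL, hypno), "misaligned")
})

test_that("event extraction applies the merge-then-duration rule", {
  lab <- rep("NOR", 200)
  lab[21:50] <- "OSA"                       # 15 s
  ev <- extract_events(lab)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$kind, "OSA")
  expect_equal(ev[[1]]$end_s - ev[[1]]$start_s, 15)

  lab2 <- rep("NOR", 200); lab2[21:32] <- "OSA"   # 6 s, isolated
  expect_length(extract_events(lab2), 0)

  lab3 <- rep("NOR", 200)
  lab3[21:40] <- "OSA"; lab3[43:62] <- "OSA"      # 10 s + 1 s gap + 10 s
  ev3 <- extract_events(lab3)
  expect_length(ev3, 1)
  expect_equal(ev3[[1]]$end_s - ev3[[1]]$start_s, 21)

  # different kinds never merge; overlap-free output
  lab4 <- rep("NOR", 200); lab4[21:50] <- "OSA"; lab4[51:80] <- "CSA"
  ev4 <- extract_events(lab4)
  expect_length(ev4, 2)
  df <- events_to_df(ev4)
  expect_true(all(df$start_s[-1] >= df$end_s[-nrow(df)]))
})

test_that("AHI arithmetic, severity bins and invariances hold", {
  hyp6 <- hypnogram_from_states(rep("sleep", 720))   # 6 h
  evs <- lapply(seq_len(30), function(i)
    event_interval(600 * i, 600 * i + 20, sample(c("OSA", "CSA", "HYP"), 1)))
  rep1 <- compute_ahi(evs, hyp6)
  expect_equal(rep1$ahi, 5)
  expect_equal(rep1$severity, "mild")
  expect_equal(compute_ahi(list(), hyp6)$ahi, 0)
  expect_equal(compute_ahi(list(), hyp6)$severity, "normal")
  expect_error(compute_ahi(evs, hypnogram_from_states(rep("wake", 10))),
               "no sleep")
  expect_error(compute_ahi(evs, list()), "empty")
  # order invariance
  rep2 <- compute_ahi(rev(evs), hyp6)
  expect_equal(rep2$ahi, rep1$ahi)
  expect_equal(rep2$counts, rep1$counts)

  expect_equal(severity_grade(1.8), "normal")
  expect_equal(severity_grade(9.4), "mild")
  expect_equal(severity_grade(21.7), "moderate")
  expect_equal(severity_grade(61.1), "severe")
  expect_equal(severity_grade(5), "mild")
  expect_equal(severity_grade(15), "moderate")
  expect_equal(severity_grade(30), "severe")
  g <- vapply(seq(0, 80, by = 0.5), severity_grade, "")
  expect_true(all(diff(match(g, c("normal", "mild", "moderate", "severe"))) >= 0))
})

test_that("evaluation metrics follow the stated formulas", {
  truth <- rep(c("NOR", "OSA", "NOR", "HYP"), times = c(100, 40, 100, 40))
  m <- evaluate(truth, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$accuracy_pct, 100)
  # P = S = 0.5 -> F1 = 0.5: half the abnormal steps missed, equal FP count
  pred <- truth
  pred[101:140] <- "NOR"     # miss all OSA (40 FN)
  pred[1:40] <- "HYP"        # 40 FP
  m2 <- evaluate(pred, truth)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$f1, 0.5)
  expect_error(evaluate(pred, character(0)), "empty")
  # event-interval inputs are rasterized onto the grid
  evs <- list(event_interval(10, 30, "OSA"))
  m3 <- evaluate(evs, evs, duration_s = 100)
  expect_equal(m3$f1, 1)
  expect_equal(sum(m3$confusion), 200)
})

test_that("confusion accuracy is trace over total", {
  m <- diag(c(5, 5, 5, 5))
  expect_equal(confusion_accuracy(m), 100)
  m2 <- matrix(c(3, 0, 0, 0, 0, 8, 0, 0, 0, 3, 11, 0, 0, 0, 3, 28), 4, 4)
  expect_equal(confusion_accuracy(m2), 100 * 50 / 56, tolerance = 1e-12)
  expect_error(confusion_accuracy(matrix(0, 2, 2)), "empty")
})
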