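# Oxygen desaturation detection, fusion of classifier output with the
# desaturation marks and sleep-wake staging, event extraction, AHI and
# severity, and evaluation metrics.

#' Detect >=3% oxygen desaturations
#'
#' The SpO2 first difference is convolved with a 20-sample all-ones kernel
#' (a 20-s accumulated drop at 1 Hz); samples where the accumulated drop
#' reaches 3% are marked, and the mark series is then shifted 20 s earlier
#' in time to compensate the physiological desaturation delay. Contiguous
#' marked runs carry their maximum accumulated drop.
#'
#' @param spo2 `signal_stream` at 1 Hz, >= 60 s.
#' @param drop_pct drop threshold in percent (default 3).
#' @param win_s accumulation window / compensation shift, seconds.
#' @return object of class `desat_marks`: logical `mark` per second
#'   (aligned to the SpO2 clock after the shift), `depth` (per-sample
#'   accumulated drop), and a data.frame `runs` (start_s, end_s,
#'   max_drop_pct).
#' @export
detect_desaturation <- function(spo2, drop_pct = 3, win_s = 20) {
  x <- spo2$samples
  n <- length(x)
  if (n < 60) stop("need at least 60 s of SpO2", call. = FALSE)
  d <- diff(x)                                  # d[i] = x[i+1] - x[i]
  acc <- as.numeric(stats::filter(d, rep(1, win_s), sides = 1))
  acc[is.na(acc)] <- cumsum(d)[is.na(acc)]      # shorter-than-window head
  # acc[i] = x[i+1] - x[i+1-win]: accumulated change ending at sample i+1
  drop <- -acc
  marked <- drop >= drop_pct                    # at sample index i+1
  mark <- rep(FALSE, n)
  depth <- rep(0, n)
  src <- which(marked) + 1L                     # sample indices on SpO2 clock
  dst <- src - win_s                            # shift 20 s earlier
  ok <- dst >= 1L
  mark[dst[ok]] <- TRUE
  depth[dst[ok]] <- drop[src[ok] - 1L]
  runs <- mark_runs(mark, depth, spo2$start_s)
  structure(list(mark = mark, depth = depth, t_s = stream_times(spo2),
                 runs = runs, drop_pct = drop_pct, win_s = win_s),
            class = "desat_marks")
}

mark_runs <- function(mark, depth, start_s) {
  r <- rle(mark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(start_s = start_s + (starts[sel] - 1),
             end_s = start_s + ends[sel],
             max_drop_pct = vapply(sel, function(k)
               max(depth[starts[k]:ends[k]]), 0))
}

#' @export
print.desat_marks <- function(x, ...) {
  cat(sprintf("<desat_marks: %d run(s), %d marked second(s)>\n",
              nrow(x$runs), sum(x$mark)))
  invisible(x)
}

#' Fuse classifier probabilities, desaturation marks and sleep-wake states
#'
#' Applies the decision rule ([decide_labels()]), then two corrections.
#' First, desaturation rescue: the marks exist to recover hypopneas whose
#' effort signature is too weak for the classifier, so for every
#' desaturation run that the classifier left (mostly) unexplained --
#' fewer than `detected_frac` of its steps carry a non-NOR argmax -- the
#' NOR steps inside the run are relabelled HYP; runs already overlapping
#' a detected event are left alone (relabelling their tails would
#' manufacture spurious extra events next to every correctly detected
#' apnea). Second, all non-NOR labels inside wake epochs are reset to NOR
#' (no events are scored during wake).
#'
#' @param probs a `prob_series` from [predict_event_probs()].
#' @param desat a `desat_marks` from [detect_desaturation()] (or NULL to
#'   skip the desaturation correction).
#' @param hypno list of [hypno_epoch()] (or NULL to treat the whole night
#'   as sleep).
#' @param detected_frac non-NOR fraction above which a desaturation run
#'   counts as already explained by the classifier.
#' @return character vector of per-step kinds, one per probability row.
#' @export
fuse <- function(probs, desat = NULL, hypno = NULL, detected_frac = 0.3) {
  labels <- decide_labels(probs)
  t_s <- as.data.frame(probs)$t_s
  if (!is.null(desat) && nrow(desat$runs)) {
    for (k in seq_len(nrow(desat$runs))) {
      in_run <- t_s >= desat$runs$start_s[k] & t_s < desat$runs$end_s[k]
      if (!any(in_run)) next
      if (mean(labels[in_run] != "NOR") < detected_frac) {
        labels[in_run & labels == "NOR"] <- "HYP"
      }
    }
  }
  if (!is.null(hypno)) {
    hy_end <- max(vapply(hypno, `[[`, 0, "start_s")) + 30
    if (any(t_s >= hy_end + 30) || any(t_s < 0)) {
      stop("probability series extends beyond the hypnogram: misaligned inputs",
           call. = FALSE)
    }
    wake <- hypno_state_at(hypno, t_s) == "wake"
    labels[wake] <- "NOR"
  }
  labels
}

#' Extract scored events from per-step labels
#'
#' Maximal same-kind runs are formed; same-kind runs separated by less
#' than `merge_gap_s` of NOR are merged first (argmax flicker should not
#' split one event), then non-NOR runs shorter than `min_dur_s` (the
#' standard 10-s scoring rule) are dropped.
#'
#' @param step_labels character vector of per-step kinds on a uniform grid.
#' @param step_s grid step in seconds (default 0.5).
#' @param t0_s time of the first step.
#' @param min_dur_s minimum event duration (default 10).
#' @param merge_gap_s NOR gap below which same-kind runs merge (default 2).
#' @return list of [event_interval()] (non-NOR only, non-overlapping).
#' @export
extract_events <- function(step_labels, step_s = 0.5, t0_s = 0,
                           min_dur_s = 10, merge_gap_s = 2) {
  r <- rle(step_labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(kind = r$values,
                     start_s = t0_s + (starts - 1) * step_s,
                     end_s = t0_s + ends * step_s)
  # merge same-kind runs separated by < merge_gap_s of NOR
  abn <- runs[runs$kind != "NOR", , drop = FALSE]
  if (!nrow(abn)) return(list())
  merged <- abn[1, , drop = FALSE]
  if (nrow(abn) > 1) {
    for (k in 2:nrow(abn)) {
      last <- nrow(merged)
      if (abn$kind[k] == merged$kind[last] &&
          abn$start_s[k] - merged$end_s[last] < merge_gap_s) {
        merged$end_s[last] <- abn$end_s[k]
      } else {
        merged <- rbind(merged, abn[k, ])
      }
    }
  }
  merged <- merged[merged$end_s - merged$start_s >= min_dur_s - 1e-9, ,
                   drop = FALSE]
  lapply(seq_len(nrow(merged)), function(k)
    event_interval(merged$start_s[k], merged$end_s[k], merged$kind[k]))
}

#' Compute the apnea-hypopnea index
#'
#' `AHI = (#OSA + #CSA + #HYP) / TST`, with total sleep time from the
#' hypnogram (number of sleep epochs x 30 s).
#'
#' @param events list of [event_interval()].
#' @param hypno nonempty list of [hypno_epoch()].
#' @return an [ahi_report()].
#' @export
compute_ahi <- function(events, hypno) {
  if (!length(hypno)) stop("empty hypnogram", call. = FALSE)
  tst_h <- sum(hypnogram_states(hypno) == "sleep") * 30 / 3600
  if (tst_h <= 0) stop("no sleep scored: AHI undefined", call. = FALSE)
  ahi_report(events, tst_h)
}

#' AHI severity grade
#'
#' Standard bins: `< 5` normal, `[5, 15)` mild, `[15, 30)` moderate,
#' `>= 30` severe; boundary values go to the upper bin.
#'
#' @param ahi nonnegative AHI value (events per hour of sleep).
#' @return one of `"normal"`, `"mild"`, `"moderate"`, `"severe"`.
#' @export
severity_grade <- function(ahi) {
  stopifnot(ahi >= 0)
  if (ahi < 5) "normal" else if (ahi < 15) "mild" else if (ahi < 30) "moderate" else "severe"
}

SEVERITY_LEVELS <- c("normal", "mild", "moderate", "severe")

#' Confusion matrix of predicted vs expert labels
#'
#' Rows are predicted, columns expert, in a fixed class order.
#'
#' @param pred,truth vectors of class labels on a common grid.
#' @param classes class order (default the four event kinds).
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(pred, truth, classes = EVENT_KINDS) {
  m <- table(factor(pred, classes), factor(truth, classes))
  m <- unclass(m)
  dimnames(m) <- list(predicted = classes, expert = classes)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Overall accuracy of a confusion matrix, in percent
#'
#' `100 * trace / total`.
#'
#' @param m a square count matrix (predicted x expert).
#' @return accuracy in percent.
#' @export
confusion_accuracy <- function(m) {
  m <- unclass(m)
  tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(m)) / tot
}

#' Evaluate predictions against expert truth
#'
#' Rasterizes event-level truth/prediction onto a common grid when
#' needed, builds the 4-class per-step confusion matrix, and computes the
#' binary abnormal-vs-NOR precision, sensitivity and
#' `F1 = 2 P S / (P + S)`, plus `|AHI_pred - AHI_truth|` when both
#' reports are supplied.
#'
#' @param pred per-step labels or a list of [event_interval()].
#' @param truth per-step labels or a list of [event_interval()].
#' @param grid_s evaluation grid step (default 0.5 s).
#' @param duration_s night length, required when rasterizing events.
#' @param ahi_pred,ahi_truth optional AHI values for the AHI difference.
#' @return list: `confusion`, `accuracy_pct`, `precision`, `sensitivity`,
#'   `f1`, `ahi_diff` (NA when not supplied).
#' @export
evaluate <- function(pred, truth, grid_s = 0.5, duration_s = NULL,
                     ahi_pred = NA_real_, ahi_truth = NA_real_) {
  if (!is.character(truth) && !length(truth)) stop("empty truth", call. = FALSE)
  as_steps <- function(z) {
    if (is.character(z)) return(z)
    if (is.null(duration_s)) stop("duration_s needed to rasterize events",
                                  call. = FALSE)
    rasterize_events(z, duration_s, grid_s)
  }
  p <- as_steps(pred); tr <- as_steps(truth)
  n <- min(length(p), length(tr))
  p <- p[seq_len(n)]; tr <- tr[seq_len(n)]
  cm <- confusion_matrix(p, tr)
  tp <- sum(p != "NOR" & tr != "NOR")
  fp <- sum(p != "NOR" & tr == "NOR")
  fn <- sum(p == "NOR" & tr != "NOR")
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(prec) && is.finite(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(confusion = cm, accuracy_pct = confusion_accuracy(cm),
       precision = prec, sensitivity = sens, f1 = f1,
       ahi_diff = abs(ahi_pred - ahi_truth))
}

#' Rasterize events onto a uniform label grid
#' @param events list of [event_interval()].
#' @param duration_s night length in seconds.
#' @param grid_s grid step (default 0.5 s).
#' @param t0_s grid origin.
#' @return character vector of per-step kinds.
#' @export
rasterize_events <- function(events, duration_s, grid_s = 0.5, t0_s = 0) {
  t_s <- seq(t0_s, duration_s - grid_s, by = grid_s)
  lab <- rep("NOR", length(t_s))
  for (ev in events) {
    lab[t_s >= ev$start_s & t_s < ev$end_s] <- ev$kind
  }
  lab
}
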