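# Triaxial accelerometer -> 1-D respiratory effort: zero-phase low-pass
# filtering and peak-count / majority-vote axis selection.

#' Zero-phase respiratory low-pass filter
#'
#' 6th-order Butterworth low-pass with a 0.8 Hz cut-off, applied
#' forward-backward (`signal::filtfilt`) so breath-peak timing is
#' undistorted.
#'
#' @param stream a `signal_stream` with `rate_hz > 1.6`.
#' @return filtered `signal_stream`, same length and rate.
#' @export
lowpass_respiratory <- function(stream) {
  fc <- 0.8
  if (stream$rate_hz <= 2 * fc) {
    stop("sampling rate ", stream$rate_hz,
         " Hz is at or below twice the 0.8 Hz cut-off; cannot filter",
         call. = FALSE)
  }
  bf <- signal::butter(6, fc / (stream$rate_hz / 2), type = "low")
  y <- signal::filtfilt(bf, stream$samples)
  signal_stream(y, stream$rate_hz, stream$start_s, stream$label)
}

# Local maxima with plateau handling: returns indices of strict-or-plateau
# peaks (plateau represented by its midpoint).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- sign(diff(x))
  # propagate the last nonzero sign across flat runs (plateau handling)
  nz <- s != 0
  pos <- cummax(seq_along(s) * nz)
  s <- ifelse(pos > 0, s[pmax(pos, 1L)], 0)
  idx <- which(diff(s) < 0) + 1L
  idx[idx > 1 & idx < n]
}

# Topographic prominence of peaks at `peaks` (indices into x).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until a higher point; key col = min over that stretch
    left <- x[seq_len(p - 1)]
    hi <- which(left > h)
    lmin <- if (length(hi)) min(left[(max(hi) + 1):(p - 1)]) else min(left)
    right <- x[(p + 1):length(x)]
    hi <- which(right > h)
    rmin <- if (length(hi)) min(right[seq_len(min(hi) - 1)]) else min(right)
    h - max(lmin, rmin)
  }, 0)
}

#' Count breathing peaks in an effort segment
#'
#' Accepts local maxima whose topographic prominence is at least
#' `0.25 * sd(segment)` and which are separated by at least 2 s (peaks
#' closer than that are resolved in favour of the taller one). The
#' prominence floor rejects noise ripples; the 2-s separation caps counts
#' near 15 per 30 s, well above the 6--9 breaths/30 s target band.
#'
#' @param segment numeric vector, one 30-s window of one axis.
#' @param rate_hz sampling rate of the segment.
#' @return nonnegative integer peak count (0 for a constant segment).
#' @export
count_breath_peaks <- function(segment, rate_hz) {
  # boxcar-decimate dense segments to ~10 Hz: breathing is < 0.5 Hz and
  # the averaging suppresses sample-level noise ripple before counting
  if (rate_hz > 12.5) {
    d <- floor(rate_hz / 10)
    nk <- (length(segment) %/% d) * d
    segment <- colMeans(matrix(segment[seq_len(nk)], d))
    rate_hz <- rate_hz / d
  }
  sdv <- stats::sd(segment)
  if (!is.finite(sdv) || sdv == 0) return(0L)
  cand <- local_maxima(segment)
  if (!length(cand)) return(0L)
  prom <- peak_prominence(segment, cand)
  cand <- cand[prom >= 0.25 * sdv]
  if (!length(cand)) return(0L)
  # enforce min separation 2 s, keeping taller peaks first
  min_sep <- 2 * rate_hz
  ord <- order(segment[cand], decreasing = TRUE)
  kept <- integer(0)
  for (i in cand[ord]) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  length(kept)
}

# distance of a peak count from the physiological 6-9 band
band_distance <- function(count, lo = 6, hi = 9) {
  ifelse(count >= lo & count <= hi, 0, pmin(abs(count - lo), abs(count - hi)))
}

#' Select the respiration-bearing axis of a triaxial stream
#'
#' The three axes are segmented by 30-s windows advancing 10 s. In each
#' segment the axis whose peak count is nearest the human breathing band
#' (6--9 peaks per 30 s) is chosen (ties at the count stage go to the
#' larger-RMS axis). The output axis at every 10-s step is the modal choice
#' of the 5 most recent segments, ties broken by the larger RMS over the
#' voting span. The selected 10-s spans are concatenated and low-pass
#' filtered ([lowpass_respiratory()]).
#'
#' Selection runs on the raw axes (the prominence rule in
#' [count_breath_peaks()] tolerates broadband content); the 0.8 Hz low-pass
#' is applied to the selected output only, so the cardiogenic band is still
#' available upstream of filtering.
#'
#' @param triax a [triaxial_stream()] of at least 70 s.
#' @param filter apply the respiratory low-pass to the output (default TRUE).
#' @return list with `effort` (`signal_stream`, label `tho`/`abd`),
#'   `raw_effort` (same axis concatenation, unfiltered) and `trace` (the
#'   per-segment `axis_trace` data.frame: peak counts, per-segment choice
#'   and the post-vote output axis per 10-s step).
#' @export
select_axis <- function(triax, filter = TRUE) {
  fs <- triax$x$rate_hz
  n <- length(triax$x$samples)
  seg_len <- as.integer(round(30 * fs))
  step <- as.integer(round(10 * fs))
  if (n < seg_len + 4 * step) {
    stop("axis selection needs at least 70 s of signal ",
         "(five 30-s segments at a 10-s step)", call. = FALSE)
  }
  ax <- list(x = triax$x$samples, y = triax$y$samples, z = triax$z$samples)
  n_seg <- (n - seg_len) %/% step + 1L
  counts <- matrix(0L, n_seg, 3, dimnames = list(NULL, c("x", "y", "z")))
  rms <- matrix(0, n_seg, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_len(n_seg)) {
    i0 <- (k - 1L) * step + 1L
    seg_idx <- i0:(i0 + seg_len - 1L)
    for (a in 1:3) {
      seg <- ax[[a]][seg_idx]
      seg <- seg - mean(seg)
      counts[k, a] <- count_breath_peaks(seg, fs)
      rms[k, a] <- sqrt(mean(seg^2))
    }
  }
  dist <- band_distance(counts)
  seg_choice <- integer(n_seg)
  for (k in seq_len(n_seg)) {
    best <- which(dist[k, ] == min(dist[k, ]))
    if (length(best) > 1) best <- best[which.max(rms[k, best])]
    seg_choice[k] <- best
  }
  # 5-segment majority vote, available from segment 5 on
  vote <- integer(n_seg)
  for (k in seq_len(n_seg)) {
    win <- max(1L, k - 4L):k
    tab <- tabulate(seg_choice[win], 3)
    best <- which(tab == max(tab))
    if (length(best) > 1) {
      vrms <- sqrt(colMeans(rms[win, best, drop = FALSE]^2))
      best <- best[which.max(vrms)]
    }
    vote[k] <- best
  }
  # output spans: 10-s span j uses the vote of segment j (warm-up spans
  # j < 5 reuse the first completed vote)
  n_span <- n %/% step
  span_axis <- vote[pmin(pmax(seq_len(n_span), 5L), n_seg)]
  out <- numeric(n_span * step)
  for (j in seq_len(n_span)) {
    idx <- ((j - 1L) * step + 1L):(j * step)
    out[idx] <- ax[[span_axis[j]]][idx]
  }
  lab <- if (triax$placement == "thoracic") "tho" else "abd"
  raw <- signal_stream(out, fs, triax$x$start_s, lab)
  trace <- data.frame(segment = seq_len(n_seg),
                      peaks_x = counts[, 1], peaks_y = counts[, 2],
                      peaks_z = counts[, 3],
                      selected = c("x", "y", "z")[seg_choice],
                      vote = c("x", "y", "z")[vote])
  trace$output_axis <- c("x", "y", "z")[vote[pmin(pmax(seq_len(n_seg), 5L), n_seg)]]
  structure(list(effort = if (filter) lowpass_respiratory(raw) else raw,
                 raw_effort = raw,
                 span_axis = c("x", "y", "z")[span_axis],
                 trace = trace),
            class = "axis_selection")
}
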