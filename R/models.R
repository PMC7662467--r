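# ECG R-peak detection (Pan-Tompkins style) and instantaneous heart rate.

#' Detect R peaks in an ECG stream
#'
#' Pan-Tompkins-style detector: 5--15 Hz band-pass, differentiation,
#' squaring, 150-ms moving-window integration, adaptive thresholding with
#' a 250-ms refractory period, and peak refinement on the band-passed
#' signal within +-50 ms.
#'
#' @param ecg `signal_stream` at >= 100 Hz, at least 60 s.
#' @return strictly increasing numeric vector of peak times in seconds
#'   (empty, with a warning, for a flat trace).
#' @export
detect_r_peaks <- function(ecg) {
  fs <- ecg$rate_hz
  if (fs < 100) stop("ECG rate must be >= 100 Hz", call. = FALSE)
  if (stream_duration(ecg) < 60) stop("need at least 60 s of ECG", call. = FALSE)
  x <- ecg$samples
  if (stats::sd(x) < .Machine$double.eps) {
    warning("flat ECG trace: no R peaks detected")
    return(numeric(0))
  }
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  d <- c(0, diff(xb)) * fs
  sq <- d^2
  win <- max(1L, as.integer(round(0.150 * fs)))
  integ <- stats::filter(sq, rep(1 / win, win), sides = 1)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  refr <- as.integer(round(0.25 * fs))
  # adaptive threshold: running signal/noise estimates
  thr <- 0.25 * max(integ[seq_len(min(length(integ), as.integer(2 * fs)))])
  spki <- thr; npki <- 0
  cand <- local_maxima(integ)
  peaks <- integer(0)
  last <- -refr
  for (i in cand) {
    if (integ[i] > npki + 0.25 * (spki - npki)) {
      if (i - last >= refr) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      } else if (length(peaks) && integ[i] > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (!length(peaks)) {
    warning("no R peaks found")
    return(numeric(0))
  }
  # refine on the band-passed signal within +-50 ms (integration delays)
  hw <- as.integer(round(0.10 * fs))
  ref <- vapply(peaks, function(i) {
    lo <- max(1L, i - hw); hi <- min(length(xb), i + hw)
    lo + which.max(xb[lo:hi]) - 1L
  }, 0L)
  ref <- sort(unique(ref))
  # drop refined duplicates closer than the refractory period
  keep <- c(TRUE, diff(ref) >= refr)
  ref <- ref[keep]
  ecg$start_s + (ref - 1) / fs
}

#' Instantaneous heart rate from R-peak times
#'
#' `IHR(r_i) = 60 / (r_i - r_(i-1))` in beats per minute, defined at each
#' peak from the second one on, then resampled to a uniform 1 Hz grid by
#' previous-value hold (the CNN input convention).
#'
#' @param r_peaks strictly increasing numeric vector of peak times
#'   (seconds), length >= 2.
#' @param duration_s grid length in seconds (default: up to the last peak).
#' @return `signal_stream` at 1 Hz of IHR values (bpm); the raw per-peak
#'   values are attached as attributes `ihr_bpm` and `ihr_t`.
#' @export
ihr <- function(r_peaks, duration_s = NULL) {
  if (length(r_peaks) < 2) stop("need at least 2 R peaks", call. = FALSE)
  if (any(diff(r_peaks) <= 0)) stop("r_peaks must be strictly increasing", call. = FALSE)
  vals <- 60 / diff(r_peaks)
  tv <- r_peaks[-1]
  if (is.null(duration_s)) duration_s <- ceiling(tv[length(tv)])
  grid <- 0:(ceiling(duration_s) - 1)
  idx <- findInterval(grid, tv)
  held <- vals[pmax(1L, idx)]        # before the first defined value, hold it
  out <- signal_stream(held, 1, 0, "ecg")
  attr(out, "ihr_bpm") <- vals
  attr(out, "ihr_t") <- tv
  out
}
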