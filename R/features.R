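# The nine per-step classifier features: amplitude ratios and frequency
# ratios of the thoracic/abdominal effort envelopes, plus five SpO2
# descriptors, assembled into 0.5-s feature frames.

#' Windowing scheme for feature extraction
#'
#' Defaults: 10-s current window (CW) advancing 0.5 s; 60-s previous window
#' (PW) immediately before the CW as the amplitude baseline; 20-s SpO2
#' segments taken with a 20-s delay after the frame time (oxygen
#' desaturation lags the respiratory event by ~20 s).
#'
#' @param cw_len_s,cw_step_s,pw_len_s,spo2_seg_s,spo2_delay_s window
#'   lengths/steps in seconds.
#' @return list of class `window_scheme`.
#' @export
window_scheme <- function(cw_len_s = 10, cw_step_s = 0.5, pw_len_s = 60,
                          spo2_seg_s = 20, spo2_delay_s = 20) {
  stopifnot(cw_len_s > 0, cw_step_s > 0, pw_len_s > 0,
            spo2_seg_s > 0, spo2_delay_s >= 0)
  structure(list(cw_len_s = cw_len_s, cw_step_s = cw_step_s,
                 pw_len_s = pw_len_s, spo2_seg_s = spo2_seg_s,
                 spo2_delay_s = spo2_delay_s), class = "window_scheme")
}

FEATURE_NAMES <- c("ar_tho", "ar_abd", "fr_tho", "fr_abd",
                   "spo2_base", "spo2_d_min", "spo2_d_max",
                   "spo2_d_mean", "spo2_d_var")

# 95% quantile with linear interpolation between order statistics
q95 <- function(x) as.numeric(stats::quantile(x, 0.95, type = 7, names = FALSE))

#' Amplitude ratio of the current window to its 60-s baseline
#'
#' `AR(n) = Q95(amp over CW(n)) / Q95(amp over PW(n))`, where Q95 is the
#' 95% quantile; the denominator is floored at `1e-8 * median(amp)` over
#' the whole night so long effort silences cannot blow the ratio up. A
#' frame whose PW is not fully covered yields `NA` (callers drop it).
#'
#' @param amp amplitude envelope `signal_stream` (from
#'   [instantaneous_amplitude()]).
#' @param scheme a [window_scheme()].
#' @param t_s frame time (CW start, seconds).
#' @param night_median precomputed `median(amp)`; computed if missing.
#' @return nonnegative amplitude ratio.
#' @export
amplitude_ratio <- function(amp, scheme = window_scheme(), t_s,
                            night_median = NULL) {
  if (is.null(night_median)) night_median <- stats::median(amp$samples)
  if (t_s - scheme$pw_len_s < amp$start_s - 1e-9) return(NA_real_)
  cw <- stream_window(amp, t_s, t_s + scheme$cw_len_s)
  pw <- stream_window(amp, t_s - scheme$pw_len_s, t_s)
  if (!length(cw) || !length(pw)) return(NA_real_)
  eps <- 1e-8 * night_median
  q95(cw) / max(q95(pw), eps, .Machine$double.xmin)
}

# trapezoid-integrated band energy of a periodogram
band_energy <- function(freq, pxx, lo, hi) {
  sel <- freq >= lo & freq <= hi
  if (sum(sel) < 2) return(0)
  f <- freq[sel]; p <- pxx[sel]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Frequency ratio: cardiac-band vs respiratory-band energy
#'
#' `FR(n) = log10( E[0.8, 1.5 Hz] / E[0.1, 0.8 Hz] )` over the current
#' window, energies obtained by trapezoidal integration of the squared
#' magnitude of the Fourier transform of the rectangular-windowed segment.
#' The 0.8--1.5 Hz band covers the cardiogenic artifact (average heart-rate
#' range); a high FR means the respiratory band is nearly silent, the
#' signature of central apnea. Computed on the axis-selected effort signal
#' *before* the 0.8 Hz low-pass so the cardiac band survives.
#'
#' @param effort effort `signal_stream` at >= 4 Hz (unfiltered).
#' @param scheme a [window_scheme()].
#' @param t_s frame time (CW start, seconds).
#' @param floor_value value returned for an all-zero segment (default -6).
#' @return FR on a log10 scale.
#' @export
frequency_ratio <- function(effort, scheme = window_scheme(), t_s,
                            floor_value = -6) {
  if (effort$rate_hz < 4) stop("frequency_ratio needs rate >= 4 Hz", call. = FALSE)
  seg <- stream_window(effort, t_s, t_s + scheme$cw_len_s)
  if (length(seg) < 2) return(NA_real_)
  seg <- seg - mean(seg)
  if (all(abs(seg) < .Machine$double.eps)) return(floor_value)
  n <- length(seg)
  sp <- Mod(stats::fft(seg))^2
  nh <- floor(n / 2) + 1
  freq <- (seq_len(nh) - 1) * effort$rate_hz / n
  num <- band_energy(freq, sp[seq_len(nh)], 0.8, 1.5)
  den <- band_energy(freq, sp[seq_len(nh)], 0.1, 0.8)
  if (num <= 0 || den <= 0) return(floor_value)
  max(log10(num / den), floor_value)
}

#' SpO2 descriptors for every 1-s sampling point
#'
#' The whole-night SpO2 trace is first normalized (subtract median, divide
#' by SD; a zero SD is replaced by 1 with a warning). For each time `t`,
#' the delayed segment `[t + delay, t + delay + 20 s)` yields the minimum,
#' maximum, mean and variance of its first difference; the normalized SpO2
#' value at `t` is kept as the baseline feature. Segments clipped by the
#' end of the recording are truncated (minimum 2 samples, else the previous
#' values are held).
#'
#' @param spo2 `signal_stream` at 1 Hz, >= 60 s.
#' @param scheme a [window_scheme()].
#' @return data.frame with `t_s` and the five feature columns, one row per
#'   1-s sampling point.
#' @export
spo2_features <- function(spo2, scheme = window_scheme()) {
  if (stream_duration(spo2) < 60) stop("need at least 60 s of SpO2", call. = FALSE)
  x <- spo2$samples
  sdv <- stats::sd(x)
  if (!is.finite(sdv) || sdv == 0) {
    warning("constant SpO2 trace: SD replaced by 1 for normalization")
    sdv <- 1
  }
  z <- (x - stats::median(x)) / sdv
  fs <- spo2$rate_hz
  n <- length(x)
  times <- spo2$start_s + (seq_len(n) - 1) / fs
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, FEATURE_NAMES[5:9]))
  seg_n <- as.integer(round(scheme$spo2_seg_s * fs))
  delay_n <- as.integer(round(scheme$spo2_delay_s * fs))
  for (i in seq_len(n)) {
    a <- i + delay_n
    b <- min(n, a + seg_n - 1L)
    if (b - a + 1L >= 2L) {
      d <- diff(z[a:b]) * fs      # per-second first derivative (normalized units)
      out[i, ] <- c(z[i], min(d), max(d), mean(d), stats::var(d))
    } else if (i > 1L) {
      out[i, ] <- out[i - 1L, ]
      out[i, 1] <- z[i]
    } else {
      out[i, ] <- c(z[i], 0, 0, 0, 0)
    }
  }
  data.frame(t_s = times, out)
}

#' Assemble the nine-dimensional feature frames
#'
#' One frame per `cw_step_s` (0.5 s) from the end of the first full 60-s
#' baseline window to the end of the recording; SpO2 descriptors (1 Hz)
#' are sample-and-held across the 0.5-s frames they cover. Trailing frames
#' whose windows extend past the end of the night use truncated windows.
#'
#' @param tho_amp,abd_amp amplitude envelopes ([instantaneous_amplitude()]).
#' @param tho_eff,abd_eff axis-selected (unfiltered) effort streams for the
#'   frequency ratio.
#' @param spo2 `signal_stream` at 1 Hz.
#' @param scheme a [window_scheme()].
#' @return data.frame of class `feature_frames`: `t_s` plus the nine
#'   feature columns, one row per 0.5-s step.
#' @export
assemble_frames <- function(tho_amp, abd_amp, tho_eff, abd_eff, spo2,
                            scheme = window_scheme()) {
  if (is.null(spo2)) stop("missing stream: spo2", call. = FALSE)
  streams <- list(tho_amp = tho_amp, abd_amp = abd_amp,
                  tho_eff = tho_eff, abd_eff = abd_eff, spo2 = spo2)
  origins <- vapply(streams, `[[`, 0, "start_s")
  if (any(abs(origins - origins[1]) > 1e-6)) {
    stop("streams are not aligned to a common origin: ",
         paste(names(streams)[abs(origins - origins[1]) > 1e-6],
               collapse = ", "), call. = FALSE)
  }
  t_end <- min(vapply(streams[1:4], function(s) s$start_s + stream_duration(s), 0))
  t0 <- origins[1] + scheme$pw_len_s
  if (t_end <= t0) stop("recording shorter than the 60-s warm-up", call. = FALSE)
  t_frames <- seq(t0, t_end, by = scheme$cw_step_s)
  med_tho <- stats::median(tho_amp$samples)
  med_abd <- stats::median(abd_amp$samples)
  sp_feat <- spo2_features(spo2, scheme)
  # sample-and-hold: frame at t uses the SpO2 feature row at floor(t)
  sp_idx <- pmin(nrow(sp_feat),
                 pmax(1L, floor((t_frames - spo2$start_s) * spo2$rate_hz) + 1L))
  ar_t <- vapply(t_frames, function(t)
    amplitude_ratio(tho_amp, scheme, t, med_tho), 0)
  ar_a <- vapply(t_frames, function(t)
    amplitude_ratio(abd_amp, scheme, t, med_abd), 0)
  fr_t <- vapply(t_frames, function(t) frequency_ratio(tho_eff, scheme, t), 0)
  fr_a <- vapply(t_frames, function(t) frequency_ratio(abd_eff, scheme, t), 0)
  frames <- data.frame(t_s = t_frames, ar_tho = ar_t, ar_abd = ar_a,
                       fr_tho = fr_t, fr_abd = fr_a,
                       sp_feat[sp_idx, FEATURE_NAMES[5:9]])
  rownames(frames) <- NULL
  # trailing frames whose (truncated) windows became empty hold the last
  # computed value; frames before the first complete row are dropped
  for (col in FEATURE_NAMES) {
    v <- frames[[col]]
    na <- which(is.na(v))
    for (i in na[na > 1]) v[i] <- v[i - 1]
    frames[[col]] <- v
  }
  frames <- frames[stats::complete.cases(frames), , drop = FALSE]
  class(frames) <- c("feature_frames", "data.frame")
  frames
}

#' Write feature frames to CSV
#' @param frames a `feature_frames` data.frame.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_frames_csv <- function(frames, path) {
  utils::write.csv(as.data.frame(frames), path, row.names = FALSE)
  invisible(path)
}
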