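# Continuous-wavelet synchrosqueezing transform (SST) and
# instantaneous-amplitude estimation of the respiratory effort signal.
#
# Analytic Morlet-type mother wavelet, log-spaced frequency grid,
# phase-transform reassignment, penalised maximum-energy ridge and
# amplitude recovery by integrating the synchrosqueezed transform over a
# small neighbourhood of the ridge.

SST_FMIN <- 0.05
SST_FMAX <- 2.0
SST_NV <- 32L            # voices per octave
SST_OMEGA0 <- 4.5        # Morlet centre frequency (rad); see vignette
SST_PAD_S <- 15          # reflect padding, seconds per side
SST_WORK_FS <- 5         # internal working rate, Hz

# Anti-aliased integer-factor decimation to about `target` Hz.
sst_decimate <- function(x, fs, target = SST_WORK_FS) {
  d <- max(1L, floor(fs / target))
  if (d == 1L) return(list(x = x, fs = fs, factor = 1L))
  bf <- signal::butter(8, 0.8 * (fs / d / 2) / (fs / 2), type = "low")
  xf <- signal::filtfilt(bf, x)
  list(x = xf[seq(1L, length(x), by = d)], fs = fs / d, factor = d)
}

# Core CWT-SST on a moderate-length vector (already at working rate).
# Returns list(Ts = complex J x T synchrosqueezed matrix, freqs).
sst_core <- function(x, fs, freqs, omega0 = SST_OMEGA0) {
  n <- length(x)
  pad <- as.integer(round(SST_PAD_S * fs))
  pad <- min(pad, n - 1L)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  np <- length(xp)
  X <- stats::fft(xp)
  k <- 0:(np - 1)
  fk <- ifelse(k <= np / 2, k, k - np) * fs / np   # Hz, signed
  J <- length(freqs)
  dl <- log(2) / SST_NV
  eps_mag <- .Machine$double.eps
  # per-scale filtering; analytic wavelet lives on positive frequencies
  keep <- (pad + 1):(pad + n)
  W <- matrix(0 + 0i, J, n)
  dW <- matrix(0 + 0i, J, n)
  pos <- fk > 0
  dfac <- 2i * pi * fk
  for (j in seq_len(J)) {
    psi <- numeric(np)
    psi[pos] <- exp(-(omega0 * fk[pos] / freqs[j] - omega0)^2 / 2)
    Xp_j <- X * psi
    W[j, ] <- (stats::fft(Xp_j, inverse = TRUE) / np)[keep]
    dW[j, ] <- (stats::fft(Xp_j * dfac, inverse = TRUE) / np)[keep]
  }
  mag <- Mod(W)
  thr <- 1e-8 * max(mag, eps_mag)
  finst <- matrix(NA_real_, nrow(W), ncol(W))  # instantaneous frequency, Hz
  okm <- mag > thr
  finst[okm] <- Im(dW[okm] / W[okm]) / (2 * pi)
  # reassignment: nearest log2-spaced bin (negative estimates drop out)
  finst[!is.na(finst) & finst <= 0] <- NA
  lbin <- round(SST_NV * log2(finst / freqs[1])) + 1
  ok <- which(is.finite(lbin) & lbin >= 1 & lbin <= J)
  tcol <- ((ok - 1) %/% J) + 1
  idx <- cbind(lbin[ok], tcol)
  vals <- W[ok] * dl
  # accumulate complex values into Ts
  re <- matrix(0, J, n); im <- matrix(0, J, n)
  lin <- (idx[, 2] - 1L) * J + idx[, 1]
  racc <- rowsum(Re(vals), lin)
  iacc <- rowsum(Im(vals), lin)
  pos <- as.integer(rownames(racc))
  re[pos] <- racc; im[pos] <- iacc
  Ts <- matrix(complex(real = re, imaginary = im), J, n)
  Ts
}

# Tone-calibration constant: sum over the scale grid of the wavelet window
# evaluated for a tone at frequency f0, times the log-measure. Constant over
# f0 in the grid interior.
sst_calibration <- function(freqs, omega0 = SST_OMEGA0) {
  f0 <- sqrt(freqs[1] * freqs[length(freqs)])
  dl <- log(2) / SST_NV
  sum(exp(-(omega0 * f0 / freqs - omega0)^2 / 2)) * dl
}

# Penalised max-energy ridge through |Ts|^2 restricted to bins [j0, j1].
# Transitions limited to +-w bins per step with quadratic penalty.
sst_ridge <- function(Ts, j0, j1, lambda = 2, w = 8L) {
  E <- Mod(Ts[j0:j1, , drop = FALSE])^2
  J <- nrow(E); n <- ncol(E)
  eps <- 1e-12 * max(E, .Machine$double.eps)
  U <- log(E + eps)
  shifts <- -w:w
  pen <- lambda * shifts^2 / 16   # quadratic in squeezed-bin jumps
  cost <- U[, 1]
  bp <- matrix(0L, J, n)
  for (t in 2:n) {
    best <- rep(-Inf, J); arg <- integer(J)
    for (si in seq_along(shifts)) {
      s <- shifts[si]
      src <- seq_len(J) - s
      val <- rep(-Inf, J)
      okj <- src >= 1 & src <= J
      val[okj] <- cost[src[okj]] - pen[si]
      upd <- val > best
      best[upd] <- val[upd]
      arg[upd] <- src[upd]
    }
    cost <- best + U[, t]
    bp[, t] <- arg
  }
  path <- integer(n)
  path[n] <- which.max(cost)
  for (t in n:2) path[t - 1] <- bp[path[t], t]
  path + j0 - 1L
}

#' Synchrosqueezing transform with ridge and amplitude extraction
#'
#' Computes a continuous-wavelet synchrosqueezed time-frequency
#' representation of a signal (analytic Morlet-type wavelet, 32
#' voices/octave over 0.05--2 Hz), extracts the dominant ridge inside
#' `band_hz` by a penalised maximum-energy path, and recovers the
#' instantaneous amplitude by integrating the synchrosqueezed transform
#' over a +-2-bin neighbourhood of the ridge. The amplitude normalisation
#' is fixed analytically so that a unit-amplitude pure tone yields
#' amplitude 1. Long signals are processed in overlapping chunks; the
#' signal is decimated internally to ~8 Hz (the analysis band ends at
#' 2 Hz).
#'
#' @param stream a `signal_stream` of at least 30 s.
#' @param band_hz numeric `(lo, hi)` ridge search band inside (0, rate/2).
#' @param keep_energy return the full time-frequency energy matrix
#'   (memory-heavy; only honoured for inputs up to ~20 min).
#' @return an object of class `tfr_result`: `times`, `freqs`, `energy`
#'   (or NULL), `ridge_hz`, `amp` (all on the internal working grid).
#' @export
sst <- function(stream, band_hz = c(0.1, 0.8), keep_energy = FALSE) {
  if (length(band_hz) != 2 || !(band_hz[1] > 0) || !(band_hz[2] > band_hz[1])) {
    stop("band_hz must be an increasing positive pair", call. = FALSE)
  }
  if (band_hz[2] >= stream$rate_hz / 2) {
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  }
  if (stream_duration(stream) < 30) {
    stop("sst needs at least 30 s of signal", call. = FALSE)
  }
  # remove DC exactly: the analytic wavelet's residual response at 0 Hz
  # (exp(-omega0^2/2)) would otherwise leak large constant offsets into
  # the envelope at the 1e-4 level
  dec <- sst_decimate(stream$samples - mean(stream$samples), stream$rate_hz)
  x <- dec$x; fs <- dec$fs
  n_oct <- log2(SST_FMAX / SST_FMIN)
  J <- as.integer(floor(n_oct * SST_NV)) + 1L
  freqs <- SST_FMIN * 2^((seq_len(J) - 1) / SST_NV)
  j0 <- max(1L, which.min(abs(freqs - band_hz[1])))
  j1 <- min(J, which.min(abs(freqs - band_hz[2])))
  Cpsi <- sst_calibration(freqs)

  chunk_s <- 600; ov_s <- 20
  n <- length(x)
  chunk <- as.integer(round(chunk_s * fs)); ov <- as.integer(round(ov_s * fs))
  starts <- seq(1L, n, by = chunk)
  amp <- numeric(n); ridge <- numeric(n)
  energy <- NULL
  for (s0 in starts) {
    s1 <- min(n, s0 + chunk - 1L)
    e0 <- max(1L, s0 - ov); e1 <- min(n, s1 + ov)
    Ts <- sst_core(x[e0:e1], fs, freqs)
    rpath <- sst_ridge(Ts, j0, j1)
    nn <- ncol(Ts)
    acc <- complex(nn)
    coloff <- (seq_len(nn) - 1L) * J
    for (off in -2L:2L) {
      rows <- pmin(J, pmax(1L, rpath + off))
      acc <- acc + Ts[coloff + rows]
    }
    a <- 2 * Mod(acc) / Cpsi
    sel <- (s0 - e0 + 1L):(s0 - e0 + (s1 - s0 + 1L))
    amp[s0:s1] <- a[sel]
    ridge[s0:s1] <- freqs[rpath[sel]]
    if (keep_energy && length(starts) == 1L && n <= 20 * 60 * fs) {
      energy <- Mod(Ts)^2
    }
  }
  structure(list(times = stream$start_s + (seq_len(n) - 1) / fs,
                 freqs = freqs, energy = energy,
                 ridge_hz = ridge, amp = amp, rate_hz = fs,
                 band_hz = band_hz),
            class = "tfr_result")
}

#' @export
print.tfr_result <- function(x, ...) {
  cat(sprintf("<tfr_result: %d steps @ %g Hz, band %g-%g Hz, median ridge %.3g Hz>\n",
              length(x$amp), x$rate_hz, x$band_hz[1], x$band_hz[2],
              stats::median(x$ridge_hz)))
  invisible(x)
}

#' Instantaneous respiratory amplitude of an effort signal
#'
#' Convenience wrapper around [sst()] with the band fixed to the
#' respiration range 0.1--0.8 Hz, returning the amplitude envelope
#' resampled onto the signal's own time grid. Because the analytic wavelet
#' carries no energy at 0 Hz, the estimate is invariant to constant
#' offsets, which suppresses posture-change baseline jumps.
#'
#' @param stream a `signal_stream` of at least 30 s.
#' @return a `signal_stream` of amplitudes, same rate/length as the input.
#' @export
instantaneous_amplitude <- function(stream) {
  r <- sst(stream, band_hz = c(0.1, 0.8))
  tt <- stream_times(stream)
  amp <- stats::approx(r$times, r$amp, xout = tt, rule = 2)$y
  signal_stream(amp, stream$rate_hz, stream$start_s, stream$label)
}
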