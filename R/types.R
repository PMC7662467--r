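#' @keywords internal
"_PACKAGE"

EVENT_KINDS <- c("NOR", "OSA", "CSA", "HYP")
STREAM_LABELS <- c("tho_x", "tho_y", "tho_z", "abd_x", "abd_y", "abd_z",
                   "tho", "abd", "spo2", "ecg")

#' Construct a uniformly sampled signal stream
#'
#' The basic container used throughout the package: a numeric vector sampled
#' at a fixed rate, anchored at a recording-relative start time (0-based
#' seconds). All intervals in the package are half-open `[start, end)`.
#'
#' @param samples numeric vector of samples.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param start_s recording-relative start time in seconds (>= 0).
#' @param label channel role, one of `tho_x`..`abd_z`, `tho`, `abd`,
#'   `spo2`, `ecg`.
#' @return An object of class `signal_stream`.
#' @export
signal_stream <- function(samples, rate_hz, start_s = 0, label = "tho") {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0,
            is.numeric(start_s), length(start_s) == 1L, start_s >= 0)
  if (!label %in% STREAM_LABELS) {
    stop("unknown stream label '", label, "'", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
                 start_s = as.numeric(start_s), label = label),
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream '%s': %d samples @ %g Hz, t = [%g, %g) s>\n",
              x$label, length(x$samples), x$rate_hz, x$start_s,
              x$start_s + length(x$samples) / x$rate_hz))
  invisible(x)
}

#' Sample times of a signal stream
#' @param stream a `signal_stream`.
#' @return numeric vector of sample times in seconds.
#' @export
stream_times <- function(stream) {
  stream$start_s + (seq_along(stream$samples) - 1) / stream$rate_hz
}

#' Duration of a signal stream in seconds
#' @param stream a `signal_stream`.
#' @return duration in seconds (length / rate).
#' @export
stream_duration <- function(stream) length(stream$samples) / stream$rate_hz

# Extract samples covering [from_s, to_s) (recording-relative seconds).
stream_window <- function(stream, from_s, to_s) {
  i0 <- floor((from_s - stream$start_s) * stream$rate_hz + 1e-9) + 1
  i1 <- ceiling((to_s - stream$start_s) * stream$rate_hz - 1e-9)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(length(stream$samples), as.integer(i1))
  if (i1 < i0) return(numeric(0))
  stream$samples[i0:i1]
}

#' Construct a triaxial accelerometer stream
#'
#' Bundles the three axes of one accelerometer placement. The axes must share
#' rate, start time and length.
#'
#' @param x,y,z `signal_stream` objects for the three axes.
#' @param placement `"thoracic"` or `"abdominal"`.
#' @return An object of class `triaxial_stream`.
#' @export
triaxial_stream <- function(x, y, z, placement = c("thoracic", "abdominal")) {
  placement <- match.arg(placement)
  for (s in list(x, y, z)) stopifnot(inherits(s, "signal_stream"))
  if (length(unique(c(x$rate_hz, y$rate_hz, z$rate_hz))) != 1L ||
      length(unique(c(x$start_s, y$start_s, z$start_s))) != 1L ||
      length(unique(c(length(x$samples), length(y$samples),
                      length(z$samples)))) != 1L) {
    stop("triaxial axes must share rate_hz, start_s and length", call. = FALSE)
  }
  structure(list(x = x, y = y, z = z, placement = placement),
            class = "triaxial_stream")
}

#' @export
print.triaxial_stream <- function(x, ...) {
  cat(sprintf("<triaxial_stream [%s]: %d samples @ %g Hz>\n", x$placement,
              length(x$x$samples), x$x$rate_hz))
  invisible(x)
}

#' Construct a scored respiratory event interval
#'
#' Half-open `[start_s, end_s)` span of one breathing state. Apneic kinds
#' (`OSA`, `CSA`, `HYP`) must last at least 10 s, per standard scoring rules.
#'
#' @param start_s,end_s interval bounds in seconds, `end_s > start_s`.
#' @param kind one of `"NOR"`, `"OSA"`, `"CSA"`, `"HYP"`.
#' @return An object of class `event_interval`.
#' @export
event_interval <- function(start_s, end_s, kind) {
  kind <- toupper(kind)
  if (identical(kind, "MIXED") || identical(kind, "MSA")) kind <- "OSA"
  stopifnot(kind %in% EVENT_KINDS, end_s > start_s, start_s >= 0)
  if (kind != "NOR" && (end_s - start_s) < 10 - 1e-9) {
    stop("apneic events must last at least 10 s", call. = FALSE)
  }
  structure(list(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                 kind = kind), class = "event_interval")
}

#' Convert a list of event intervals to a data frame
#' @param events list of `event_interval`.
#' @return data.frame with columns start_s, end_s, kind.
#' @export
events_to_df <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  data.frame(start_s = vapply(events, `[[`, 0, "start_s"),
             end_s = vapply(events, `[[`, 0, "end_s"),
             kind = vapply(events, `[[`, "", "kind"),
             stringsAsFactors = FALSE)
}

#' Convert a data frame of intervals to event_interval objects
#' @param df data.frame with columns start_s, end_s, kind.
#' @return list of `event_interval`.
#' @export
df_to_events <- function(df) {
  lapply(seq_len(nrow(df)),
         function(i) event_interval(df$start_s[i], df$end_s[i], df$kind[i]))
}

#' Construct a 30-s hypnogram epoch
#' @param start_s epoch start, a nonnegative multiple of 30 s.
#' @param state `"sleep"` or `"wake"`.
#' @return An object of class `hypno_epoch`.
#' @export
hypno_epoch <- function(start_s, state = c("sleep", "wake")) {
  state <- match.arg(state)
  stopifnot(start_s >= 0, abs(start_s %% 30) < 1e-9)
  structure(list(start_s = as.numeric(start_s), state = state),
            class = "hypno_epoch")
}

#' Build a hypnogram from a state vector
#' @param states character vector of `"sleep"`/`"wake"`, one per 30-s epoch
#'   starting at t = 0.
#' @return list of `hypno_epoch` tiling the recording.
#' @export
hypnogram_from_states <- function(states) {
  lapply(seq_along(states),
         function(i) hypno_epoch((i - 1) * 30, states[i]))
}

#' Extract the state vector of a hypnogram
#' @param hypno list of [hypno_epoch()].
#' @return character vector of `"sleep"`/`"wake"`, one per epoch.
#' @export
hypnogram_states <- function(hypno) vapply(hypno, `[[`, "", "state")

# sleep/wake state at an arbitrary time, via the 30-s grid anchored at 0
hypno_state_at <- function(hypno, t_s) {
  idx <- pmin(length(hypno), pmax(1L, floor(t_s / 30) + 1L))
  hypnogram_states(hypno)[idx]
}

#' Bundle the raw streams and annotations of one overnight recording
#'
#' @param tho_taa,abd_taa `triaxial_stream` objects (thoracic / abdominal).
#' @param spo2 `signal_stream` at (nominally) 1 Hz.
#' @param ecg optional `signal_stream`; may be omitted when `r_peaks` given.
#' @param r_peaks optional strictly increasing numeric vector of R-peak
#'   times in seconds.
#' @param events optional list of `event_interval` (expert annotations).
#' @param hypnogram optional list of `hypno_epoch`.
#' @return An object of class `recording`.
#' @export
recording <- function(tho_taa, abd_taa, spo2, ecg = NULL, r_peaks = NULL,
                      events = NULL, hypnogram = NULL) {
  stopifnot(inherits(tho_taa, "triaxial_stream"),
            inherits(abd_taa, "triaxial_stream"),
            inherits(spo2, "signal_stream"))
  if (is.null(ecg) && is.null(r_peaks)) {
    stop("recording needs an ecg stream or a precomputed r_peaks list",
         call. = FALSE)
  }
  if (!is.null(r_peaks) && length(r_peaks) > 1 && any(diff(r_peaks) <= 0)) {
    stop("r_peaks must be strictly increasing", call. = FALSE)
  }
  structure(list(tho_taa = tho_taa, abd_taa = abd_taa, spo2 = spo2,
                 ecg = ecg, r_peaks = r_peaks, events = events,
                 hypnogram = hypnogram),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %.1f min TAA @ %g Hz, SpO2 @ %g Hz%s%s%s>\n",
              stream_duration(x$tho_taa$x) / 60, x$tho_taa$x$rate_hz,
              x$spo2$rate_hz,
              if (!is.null(x$ecg)) sprintf(", ECG @ %g Hz", x$ecg$rate_hz) else "",
              if (!is.null(x$events)) sprintf(", %d events", length(x$events)) else "",
              if (!is.null(x$hypnogram)) sprintf(", %d epochs", length(x$hypnogram)) else ""))
  invisible(x)
}

#' Duration of a recording in seconds (effort-stream span)
#' @param rec a `recording`.
#' @return seconds.
#' @export
recording_duration <- function(rec) stream_duration(rec$tho_taa$x)

#' Construct an AHI report
#'
#' @param events list of scored `event_interval` (apneic kinds only or mixed;
#'   NOR intervals are ignored for counting).
#' @param tst_h total sleep time in hours (> 0).
#' @return An object of class `ahi_report` with fields `ahi`, `severity`,
#'   `counts`, `tst_h`, `events`.
#' @export
ahi_report <- function(events, tst_h) {
  stopifnot(tst_h > 0)
  kinds <- if (length(events)) vapply(events, `[[`, "", "kind") else character(0)
  counts <- vapply(c("OSA", "CSA", "HYP"),
                   function(k) sum(kinds == k), 0L)
  ahi <- sum(counts) / tst_h
  structure(list(ahi = ahi, severity = severity_grade(ahi), counts = counts,
                 tst_h = as.numeric(tst_h),
                 events = events[kinds != "NOR"]),
            class = "ahi_report")
}

#' @export
print.ahi_report <- function(x, ...) {
  cat(sprintf("<ahi_report: AHI %.2f /h (%s), TST %.2f h, OSA %d / CSA %d / HYP %d>\n",
              x$ahi, x$severity, x$tst_h,
              x$counts[["OSA"]], x$counts[["CSA"]], x$counts[["HYP"]]))
  invisible(x)
}
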