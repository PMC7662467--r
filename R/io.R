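# Readers and writers: CSV signal bundles (one file per rate group), a
# minimal EDF implementation, annotation CSVs and JSON AHI reports.

TAA_COLS <- c("tho_x", "tho_y", "tho_z", "abd_x", "abd_y", "abd_z")

#' Clean an SpO2 trace
#'
#' Replaces non-finite values and values outside the physiologically
#' plausible range (50--100 %) -- typically sensor dropouts recorded as 0 --
#' by linear interpolation from the nearest valid neighbours. Leading or
#' trailing invalid spans take the nearest valid value.
#'
#' @param stream an `spo2` `signal_stream`.
#' @return cleaned `signal_stream` of the same length.
#' @export
clean_spo2 <- function(stream) {
  x <- stream$samples
  ok <- is.finite(x) & x >= 50 & x <= 100
  if (!any(ok)) stop("SpO2 trace contains no valid samples", call. = FALSE)
  if (!all(ok)) {
    x <- stats::approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
  }
  signal_stream(x, stream$rate_hz, stream$start_s, "spo2")
}

#' Read an overnight recording from CSV or EDF files
#'
#' The CSV layout uses one file per rate group: a TAA file with columns
#' `tho_x..abd_z` (50 Hz by default), an SpO2 file with column `spo2`
#' (1 Hz) and optionally an ECG file with column `ecg` (500 Hz), plus
#' optional annotation CSVs (`events`: start_s,end_s,kind;
#' `hypnogram`: start_s,state). An EDF path bundles the signal channels in
#' one file; channel labels are matched to roles case-insensitively.
#' SpO2 is cleaned at read time (see [clean_spo2()]); a `MIXED`/`MSA` event
#' kind is remapped to `OSA` on ingest.
#'
#' @param paths named list of file paths. For `format = "csv"`: `taa`,
#'   `spo2`, optional `ecg`, `r_peaks`, `events`, `hypnogram`. For
#'   `format = "edf"`: `edf`, plus the optional annotation CSVs.
#' @param format `"csv"` or `"edf"`.
#' @param rates named list of sampling rates for the CSV reader
#'   (`taa`, `spo2`, `ecg`).
#' @return a [recording()].
#' @export
read_recording <- function(paths, format = c("csv", "edf"),
                           rates = list(taa = 50, spo2 = 1, ecg = 500)) {
  format <- match.arg(format)
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if (format == "csv") {
    if (is.null(paths$taa)) stop("missing mandatory channel file: taa (6-axis effort)", call. = FALSE)
    if (is.null(paths$spo2)) stop("missing mandatory channel file: spo2", call. = FALSE)
    taa <- utils::read.csv(paths$taa)
    missing_cols <- setdiff(TAA_COLS, names(taa))
    if (length(missing_cols)) {
      stop("TAA file lacks channel column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    sp <- utils::read.csv(paths$spo2)
    if (!"spo2" %in% names(sp)) stop("SpO2 file lacks 'spo2' column", call. = FALSE)
    mk <- function(col, lab) signal_stream(taa[[col]], rates$taa, 0, lab)
    tho <- triaxial_stream(mk("tho_x", "tho_x"), mk("tho_y", "tho_y"),
                           mk("tho_z", "tho_z"), "thoracic")
    abd <- triaxial_stream(mk("abd_x", "abd_x"), mk("abd_y", "abd_y"),
                           mk("abd_z", "abd_z"), "abdominal")
    spo2 <- clean_spo2(signal_stream(sp$spo2, rates$spo2, 0, "spo2"))
    ecg <- NULL
    if (!is.null(paths$ecg)) {
      ec <- utils::read.csv(paths$ecg)
      if (!"ecg" %in% names(ec)) stop("ECG file lacks 'ecg' column", call. = FALSE)
      ecg <- signal_stream(ec$ecg, rates$ecg, 0, "ecg")
    }
  } else {
    if (is.null(paths$edf)) stop("missing mandatory file: edf", call. = FALSE)
    chans <- read_edf(paths$edf)
    labs <- tolower(names(chans))
    get_chan <- function(role) {
      i <- match(role, labs)
      if (is.na(i)) stop("missing mandatory channel: ", role, call. = FALSE)
      chans[[i]]
    }
    mk <- function(role) {
      ch <- get_chan(role)
      signal_stream(ch$samples, ch$rate_hz, 0, role)
    }
    tho <- triaxial_stream(mk("tho_x"), mk("tho_y"), mk("tho_z"), "thoracic")
    abd <- triaxial_stream(mk("abd_x"), mk("abd_y"), mk("abd_z"), "abdominal")
    spo2 <- clean_spo2(mk("spo2"))
    ecg <- if ("ecg" %in% labs) mk("ecg") else NULL
  }
  r_peaks <- NULL
  if (!is.null(paths$r_peaks)) {
    r_peaks <- utils::read.csv(paths$r_peaks)$t_s
  }
  events <- NULL
  if (!is.null(paths$events)) {
    events <- read_events_csv(paths$events)
  }
  hypno <- NULL
  if (!is.null(paths$hypnogram)) {
    hy <- utils::read.csv(paths$hypnogram)
    hypno <- lapply(seq_len(nrow(hy)),
                    function(i) hypno_epoch(hy$start_s[i], hy$state[i]))
  }
  recording(tho, abd, spo2, ecg = ecg, r_peaks = r_peaks,
            events = events, hypnogram = hypno)
}

#' Write a recording to the CSV bundle layout
#' @param rec a [recording()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, e.g. `"truth_"` for simulator ground truth
#'   annotation files.
#' @return (invisibly) named list of the files written.
#' @export
write_recording_csv <- function(rec, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(dir, paste0(name))
  taa <- data.frame(tho_x = rec$tho_taa$x$samples, tho_y = rec$tho_taa$y$samples,
                    tho_z = rec$tho_taa$z$samples, abd_x = rec$abd_taa$x$samples,
                    abd_y = rec$abd_taa$y$samples, abd_z = rec$abd_taa$z$samples)
  files <- list(taa = fp("taa.csv"), spo2 = fp("spo2.csv"))
  utils::write.csv(taa, files$taa, row.names = FALSE)
  utils::write.csv(data.frame(spo2 = rec$spo2$samples), files$spo2,
                   row.names = FALSE)
  if (!is.null(rec$ecg)) {
    files$ecg <- fp("ecg.csv")
    utils::write.csv(data.frame(ecg = rec$ecg$samples), files$ecg,
                     row.names = FALSE)
  }
  if (!is.null(rec$r_peaks)) {
    files$r_peaks <- fp(paste0(prefix, "r_peaks.csv"))
    utils::write.csv(data.frame(t_s = rec$r_peaks), files$r_peaks,
                     row.names = FALSE)
  }
  if (!is.null(rec$events)) {
    files$events <- fp(paste0(prefix, "events.csv"))
    write_events_csv(rec$events, files$events)
  }
  if (!is.null(rec$hypnogram)) {
    files$hypnogram <- fp(paste0(prefix, "hypnogram.csv"))
    utils::write.csv(data.frame(
      start_s = vapply(rec$hypnogram, `[[`, 0, "start_s"),
      state = hypnogram_states(rec$hypnogram)), files$hypnogram,
      row.names = FALSE)
  }
  invisible(files)
}

#' Read / write event annotation CSVs
#'
#' Columns `start_s,end_s,kind`; `MIXED`/`MSA` kinds are remapped to `OSA`
#' on read (mixed apnea shares the obstructive mechanism).
#' @param path CSV path.
#' @return list of [event_interval()].
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("start_s", "end_s", "kind")
  if (!all(need %in% names(df))) {
    stop("annotation file ", path, " must have columns start_s,end_s,kind",
         call. = FALSE)
  }
  df_to_events(df)
}

#' @rdname read_events_csv
#' @param events list of [event_interval()].
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events_to_df(events), path, row.names = FALSE)
  invisible(path)
}

#' Write an AHI report to JSON
#'
#' @param report an [ahi_report()].
#' @param path output JSON path.
#' @return (invisibly) the path.
#' @export
write_report <- function(report, path) {
  obj <- list(ahi = report$ahi, severity = report$severity,
              counts = as.list(report$counts), tst_h = report$tst_h,
              events = events_to_df(report$events))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an AHI report written by [write_report()]
#' @param path JSON path.
#' @return an [ahi_report()].
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  events <- if (is.data.frame(obj$events) && nrow(obj$events)) {
    df_to_events(obj$events)
  } else list()
  rep <- ahi_report(events, obj$tst_h)
  if (abs(rep$ahi - obj$ahi) > 1e-9 * max(1, abs(obj$ahi))) {
    stop("report file is inconsistent: stored AHI does not match events/tst",
         call. = FALSE)
  }
  rep
}

# ---- minimal EDF ----------------------------------------------------------
# Plain EDF: 256-byte ASCII header, 256 bytes per signal header field block,
# then data records of int16 little-endian samples. One-second records.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

#' Write signal channels to a minimal EDF file
#'
#' @param channels named list; each element a list with `samples` and
#'   `rate_hz` (integer samples per 1-s data record). Channel names become
#'   EDF labels.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_edf <- function(channels, path) {
  ns <- length(channels)
  rates <- vapply(channels, function(ch) ch$rate_hz, 0)
  if (any(rates != round(rates))) {
    stop("EDF writer requires integer samples per 1-s record", call. = FALSE)
  }
  durs <- vapply(channels, function(ch) length(ch$samples) / ch$rate_hz, 0)
  n_rec <- floor(min(durs))
  if (n_rec < 1) stop("channels shorter than one 1-s record", call. = FALSE)
  pmin_ <- vapply(channels, function(ch) min(ch$samples), 0)
  pmax_ <- vapply(channels, function(ch) max(ch$samples), 0)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(edf_pad(x, n), con, nchars = n, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (1L + ns)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (nm in names(channels)) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)                     # transducer
  for (i in seq_len(ns)) wr("", 8)                      # dimension
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 7), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)                     # prefiltering
  for (i in seq_len(ns)) wr(as.character(rates[i]), 8)  # samples per record
  for (i in seq_len(ns)) wr("", 32)                     # reserved
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- channels[[i]]$samples[seq_len(n_rec * rates[i])]
    d <- round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * rates[i] + 1):(r * rates[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a minimal EDF file
#' @param path EDF path.
#' @return named list of channels, each with `samples` and `rate_hz`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unparseable EDF header in ", path, call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  out <- lapply(seq_len(ns), function(i) {
    list(samples = numeric(n_rec * spr[i]), rate_hz = spr[i] / rec_dur)
  })
  names(out) <- labels
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                   endian = "little")
      phys <- pmin_[i] + (d - dmin_[i]) * (pmax_[i] - pmin_[i]) /
        (dmax_[i] - dmin_[i])
      out[[i]]$samples[((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  out
}

#' Write a recording to a single EDF file
#' @param rec a [recording()].
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_recording_edf <- function(rec, path) {
  channels <- list(
    tho_x = list(samples = rec$tho_taa$x$samples, rate_hz = rec$tho_taa$x$rate_hz),
    tho_y = list(samples = rec$tho_taa$y$samples, rate_hz = rec$tho_taa$y$rate_hz),
    tho_z = list(samples = rec$tho_taa$z$samples, rate_hz = rec$tho_taa$z$rate_hz),
    abd_x = list(samples = rec$abd_taa$x$samples, rate_hz = rec$abd_taa$x$rate_hz),
    abd_y = list(samples = rec$abd_taa$y$samples, rate_hz = rec$abd_taa$y$rate_hz),
    abd_z = list(samples = rec$abd_taa$z$samples, rate_hz = rec$abd_taa$z$rate_hz),
    spo2 = list(samples = rec$spo2$samples, rate_hz = rec$spo2$rate_hz))
  if (!is.null(rec$ecg)) {
    channels$ecg <- list(samples = rec$ecg$samples, rate_hz = rec$ecg$rate_hz)
  }
  write_edf(channels, path)
}
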