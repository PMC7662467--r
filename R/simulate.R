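# Synthetic overnight recordings with ground truth: quasi-periodic
# respiratory effort projected onto posture-dependent accelerometer axes,
# scripted OSA (paradoxical effort), CSA (effort silence + cardiogenic
# artifact), HYP (30% amplitude reduction) events, delayed SpO2
# desaturations, a state-dependent RR process rendered as ECG, and wake
# bouts with altered heart-rate statistics.

#' Simulator configuration
#'
#' Defaults encode the statistical structure the pipeline assumes: breaths
#' at 0.2--0.3 Hz (6--9 per 30 s), event durations N(20.2, 3.4) s
#' truncated at 10 s, desaturation delays N(19.3, 9.6) s truncated at 5 s,
#' desaturation depths uniform in 3.2--8% (kept clear of the 3% detection
#' threshold so scripted counts are recoverable despite the slow SpO2
#' baseline drift), a ~1.1 Hz cardiogenic artifact at 3% of baseline
#' effort during central apneas, and a default night of 30 min with ~8
#' events for desk-scale runs.
#'
#' @param duration_h night length in hours.
#' @param seed RNG seed.
#' @param event_rate_per_h named per-kind event rates (per hour of sleep).
#' @param event_duration_mean_s,event_duration_sd_s,event_duration_min_s
#'   truncated-normal event durations.
#' @param desat_delay_mean_s,desat_delay_sd_s,desat_delay_min_s
#'   truncated-normal event-to-desaturation delays.
#' @param desat_depth_pct length-2 uniform range of desaturation depths.
#' @param breath_hz length-2 range of the drifting breathing frequency.
#' @param posture_change_rate_per_h Poisson rate of posture changes.
#' @param wake_bouts list(count, len_range_s): scripted wake bouts.
#' @param cardiogenic_amp cardiogenic component amplitude (relative).
#' @param noise_sd accelerometer white-noise SD (relative).
#' @param taa_rate_hz,spo2_rate_hz,ecg_rate_hz stream rates.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration_h = 0.5, seed = 1L,
                       event_rate_per_h = c(OSA = 6, CSA = 4, HYP = 6),
                       event_duration_mean_s = 20.2,
                       event_duration_sd_s = 3.4,
                       event_duration_min_s = 10,
                       desat_delay_mean_s = 19.3,
                       desat_delay_sd_s = 9.6,
                       desat_delay_min_s = 5,
                       desat_depth_pct = c(3.2, 8),
                       breath_hz = c(0.2, 0.3),
                       posture_change_rate_per_h = 1,
                       wake_bouts = list(count = 1, len_range_s = c(120, 300)),
                       cardiogenic_amp = 0.03,
                       noise_sd = 0.05,
                       taa_rate_hz = 50, spo2_rate_hz = 1,
                       ecg_rate_hz = 500) {
  stopifnot(duration_h > 0, all(event_rate_per_h >= 0),
            desat_depth_pct[1] > 3, length(breath_hz) == 2)
  structure(as.list(environment()), class = "sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lo)) x[x < lo] <- stats::rnorm(sum(x < lo), mean, sd)
  x
}

# cosine-ramped indicator of [a, b) with ramp_s edges
smooth_gate <- function(t, a, b, ramp_s = 2) {
  up <- stats::plogis((t - a) / (ramp_s / 6))
  dn <- stats::plogis((b - t) / (ramp_s / 6))
  up * dn
}

# schedule wake epochs; returns character state per 30-s epoch
sim_hypnogram <- function(cfg, n_epochs) {
  states <- rep("sleep", n_epochs)
  nb <- cfg$wake_bouts$count
  if (nb > 0 && n_epochs > 6) {
    for (b in seq_len(nb)) {
      len_ep <- max(1L, round(stats::runif(1, cfg$wake_bouts$len_range_s[1],
                                           cfg$wake_bouts$len_range_s[2]) / 30))
      for (try in 1:50) {
        s0 <- sample.int(n_epochs - len_ep + 1L, 1)
        span <- s0:(s0 + len_ep - 1L)
        # keep a sleep epoch of margin around bouts
        margin <- max(1L, s0 - 1L):min(n_epochs, s0 + len_ep)
        if (all(states[margin] == "sleep")) { states[span] <- "wake"; break }
      }
    }
  }
  states
}

# place events inside sleep spans with a minimum start gap
sim_events <- function(cfg, states, dur_s) {
  tst_h <- sum(states == "sleep") * 30 / 3600
  kinds <- rep(names(cfg$event_rate_per_h),
               times = round(cfg$event_rate_per_h * tst_h))
  if (!length(kinds)) return(list())
  kinds <- sample(kinds)
  durs <- rtruncnorm1(length(kinds), cfg$event_duration_mean_s,
                      cfg$event_duration_sd_s, cfg$event_duration_min_s)
  wake_t <- which(states == "wake")
  in_sleep <- function(a, b) {
    ep <- floor(a / 30):floor((b - 1e-9) / 30)
    ep <- ep[ep < length(states)]
    all(states[ep + 1] == "sleep")
  }
  placed <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       kind = character(0))
  min_gap <- 90
  for (k in seq_along(kinds)) {
    done <- FALSE
    for (try in 1:300) {
      st <- stats::runif(1, 90, dur_s - durs[k] - 60)
      en <- st + durs[k]
      if (!in_sleep(st, en)) next
      if (nrow(placed) &&
          any(st < placed$start_s + min_gap & placed$start_s < st + min_gap)) next
      placed <- rbind(placed, data.frame(start_s = st, end_s = en,
                                         kind = kinds[k]))
      done <- TRUE
      break
    }
    if (!done) {
      stop("event load exceeds the night: could not place ", length(kinds),
           " events in ", round(tst_h, 2), " h of sleep", call. = FALSE)
    }
  }
  placed <- placed[order(placed$start_s), ]
  df_to_events(placed)
}

#' Generate a fully labelled synthetic overnight recording
#'
#' Deterministic given `cfg$seed`. Returns the raw multichannel recording
#' (with truth events, hypnogram and R-peak times attached) plus the
#' ground-truth AHI report computed from the scripted events and
#' hypnogram.
#'
#' Event signatures: OSA -- thoracic envelope reduced with the thoracic
#' and abdominal excursions pushed into antiphase (paradoxical effort,
#' near-cancelling "airflow"); CSA -- both envelopes collapse to ~3% of
#' baseline with a ~1.1 Hz cardiogenic ripple; HYP -- both envelopes at
#' 70% of baseline. Every event schedules a >=3% SpO2 desaturation with
#' the configured delay (10-s linear decline, exponential recovery,
#' tau = 15 s). Wake bouts raise the mean and variance of heart rate.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (a [recording()]) and `truth`
#'   (an [ahi_report()]).
#' @export
generate_recording <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  dur_s <- cfg$duration_h * 3600
  n_ep <- floor(dur_s / 30)
  states <- sim_hypnogram(cfg, n_ep)
  hypno <- hypnogram_from_states(states)
  events <- sim_events(cfg, states, dur_s)
  fs <- cfg$taa_rate_hz
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  n <- length(t)

  # drifting breathing frequency and baseline amplitude
  f_lo <- cfg$breath_hz[1]; f_hi <- cfg$breath_hz[2]
  ph_dr <- stats::runif(2, 0, 2 * pi)
  # drift kept interior to the range so 30-s windows genuinely hold 6-9
  # breaths (a sinusoid dwells at its extremes; at exactly 0.2 Hz a window
  # holds 6 cycles and edge truncation yields ambiguous counts of 5)
  f_t <- f_lo + (f_hi - f_lo) * (0.5 + 0.35 * sin(2 * pi * t / 600 + ph_dr[1]))
  phase <- cumsum(2 * pi * f_t / fs)
  A_t <- 1 + 0.1 * sin(2 * pi * t / 300 + ph_dr[2])

  env_tho <- rep(1, n); env_abd <- rep(1, n)
  dphi <- rep(0.15 * pi, n)       # small baseline THO-ABD phase offset
  cardio <- rep(0, n)
  for (ev in events) {
    g <- smooth_gate(t, ev$start_s, ev$end_s)
    if (ev$kind == "OSA") {
      # asymmetric paradoxical effort with antiphase envelope modulation;
      # 14-s alternation survives the envelope estimator's ~3-s smoothing
      mod <- sin(2 * pi * (t - ev$start_s) / 14)
      env_tho <- env_tho * (1 - g) + g * 0.30 * (1 + 0.5 * mod) * env_tho
      env_abd <- env_abd * (1 - g) + g * 1.00 * (1 - 0.5 * mod) * env_abd
      dphi <- dphi + g * (0.95 * pi - 0.15 * pi)
    } else if (ev$kind == "CSA") {
      env_tho <- env_tho * (1 - g * 0.97)
      env_abd <- env_abd * (1 - g * 0.97)
      cardio <- cardio + g * cfg$cardiogenic_amp
    } else if (ev$kind == "HYP") {
      env_tho <- env_tho * (1 - g * 0.30)
      env_abd <- env_abd * (1 - g * 0.30)
    }
  }
  cardio_wave <- sin(2 * pi * 1.1 * t)
  tho1 <- A_t * env_tho * sin(phase) + cardio * cardio_wave
  abd1 <- A_t * env_abd * sin(phase + dphi) + cardio * cardio_wave

  # posture segments: respiration projected on a dominant axis
  pc_times <- sort(stats::runif(stats::rpois(1, cfg$posture_change_rate_per_h *
                                               cfg$duration_h), 0, dur_s))
  seg_bounds <- c(0, pc_times, dur_s)
  project <- function(effort) {
    axes <- matrix(0, n, 3)
    dominant <- character(length(seg_bounds) - 1)
    prev_dom <- 0L
    for (s in seq_len(length(seg_bounds) - 1)) {
      dom <- sample(setdiff(1:3, prev_dom), 1)
      prev_dom <- dom
      u <- stats::rnorm(3, 0, 0.12)
      u[dom] <- u[dom] + 1
      u <- u / sqrt(sum(u^2))
      if (abs(u[dom]) < max(abs(u[-dom])) * 1.5) {
        u <- rep(0.1, 3); u[dom] <- 1; u <- u / sqrt(sum(u^2))
      }
      sel <- t >= seg_bounds[s] & t < seg_bounds[s + 1] + 1e-9
      for (a in 1:3) axes[sel, a] <- u[a] * effort[sel]
      dominant[s] <- c("x", "y", "z")[dom]
    }
    axes <- axes + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd), n, 3)
    list(axes = axes, dominant = dominant)
  }
  ptho <- project(tho1)
  pabd <- project(abd1)
  mkax <- function(p, i, lab) signal_stream(p$axes[, i], fs, 0, lab)
  tho_taa <- triaxial_stream(mkax(ptho, 1, "tho_x"), mkax(ptho, 2, "tho_y"),
                             mkax(ptho, 3, "tho_z"), "thoracic")
  abd_taa <- triaxial_stream(mkax(pabd, 1, "abd_x"), mkax(pabd, 2, "abd_y"),
                             mkax(pabd, 3, "abd_z"), "abdominal")

  # SpO2 with scripted desaturations
  tt1 <- 0:(ceiling(dur_s) - 1)
  spo2_v <- 97 + 0.7 * sin(2 * pi * tt1 / 1800 + stats::runif(1, 0, 2 * pi))
  desat <- data.frame(onset_s = numeric(0), depth = numeric(0))
  if (length(events)) {
    onsets <- vapply(events, `[[`, 0, "start_s") +
      rtruncnorm1(length(events), cfg$desat_delay_mean_s,
                  cfg$desat_delay_sd_s, cfg$desat_delay_min_s)
    depths <- stats::runif(length(events), cfg$desat_depth_pct[1],
                           cfg$desat_depth_pct[2])
    ord <- order(onsets)
    onsets <- onsets[ord]; depths <- depths[ord]
    if (length(onsets) > 1) {
      for (k in 2:length(onsets)) {
        if (onsets[k] < onsets[k - 1] + 50) onsets[k] <- onsets[k - 1] + 50
      }
    }
    keep <- onsets + 15 < dur_s
    desat <- data.frame(onset_s = onsets[keep], depth = depths[keep])
    for (k in seq_len(nrow(desat))) {
      o <- desat$onset_s[k]; dp <- desat$depth[k]
      rel <- tt1 - o
      contrib <- ifelse(rel < 0, 0,
                        ifelse(rel < 10, dp * rel / 10,
                               ifelse(rel < 50, dp * exp(-(rel - 10) / 15), 0)))
      spo2_v <- spo2_v - contrib
    }
  }
  spo2 <- signal_stream(spo2_v, cfg$spo2_rate_hz, 0, "spo2")

  # RR process and ECG rendering
  r_peaks <- numeric(0)
  tcur <- stats::runif(1, 0, 0.5)
  while (tcur < dur_s) {
    wake_now <- states[min(n_ep, floor(tcur / 30) + 1)] == "wake"
    rr <- if (wake_now) 0.75 + stats::rnorm(1, 0, 0.06)
          else 1.0 + stats::rnorm(1, 0, 0.02)
    rr <- max(0.4, rr)
    r_peaks <- c(r_peaks, tcur)
    tcur <- tcur + rr
  }
  fe <- cfg$ecg_rate_hz
  ne <- as.integer(dur_s * fe)
  ecg_v <- stats::rnorm(ne, 0, 0.02)
  qrs_half <- as.integer(0.03 * fe)
  qrs <- exp(-((seq(-qrs_half, qrs_half)) / (0.012 * fe))^2)
  for (rp in r_peaks) {
    c0 <- as.integer(round(rp * fe)) + 1L
    idx <- (c0 - qrs_half):(c0 + qrs_half)
    ok <- idx >= 1 & idx <= ne
    ecg_v[idx[ok]] <- ecg_v[idx[ok]] + qrs[ok]
  }
  ecg <- signal_stream(ecg_v, fe, 0, "ecg")

  rec <- recording(tho_taa, abd_taa, spo2, ecg = ecg, r_peaks = r_peaks,
                   events = events, hypnogram = hypno)
  attr(rec, "truth_axes") <- list(tho = list(bounds = seg_bounds,
                                             dominant = ptho$dominant),
                                  abd = list(bounds = seg_bounds,
                                             dominant = pabd$dominant))
  attr(rec, "truth_desat") <- desat
  truth <- compute_ahi(events, hypno)
  list(recording = rec, truth = truth)
}

#' Run the feature pipeline on one recording
#'
#' Axis selection on both accelerometers, synchrosqueezing amplitude
#' envelopes, and the nine-feature frame assembly.
#'
#' @param rec a [recording()].
#' @param scheme a [window_scheme()].
#' @return list: `frames` (a `feature_frames` data.frame), `tho`, `abd`
#'   (axis-selection results), `tho_amp`, `abd_amp` (envelopes).
#' @export
pipeline_features <- function(rec, scheme = window_scheme()) {
  tho_sel <- select_axis(rec$tho_taa)
  abd_sel <- select_axis(rec$abd_taa)
  tho_amp <- instantaneous_amplitude(tho_sel$effort)
  abd_amp <- instantaneous_amplitude(abd_sel$effort)
  frames <- assemble_frames(tho_amp, abd_amp, tho_sel$raw_effort,
                            abd_sel$raw_effort, rec$spo2, scheme)
  list(frames = frames, tho = tho_sel, abd = abd_sel,
       tho_amp = tho_amp, abd_amp = abd_amp)
}

# per-frame truth kind: the event kind covering the middle of the frame's
# current window
frame_truth_labels <- function(frames, events, cw_len_s = 10) {
  mid <- frames$t_s + cw_len_s / 2
  lab <- rep("NOR", length(mid))
  for (ev in events) {
    lab[mid >= ev$start_s & mid < ev$end_s] <- ev$kind
  }
  lab
}

# sleep-wake training windows for one recording (5-min context per epoch)
sleepwake_windows <- function(rec, cfg = sleepwake_config()) {
  chans <- sleepwake_channels(rec)
  dur <- recording_duration(rec)
  n_ep <- floor(dur / cfg$epoch_s)
  x <- array(0, c(n_ep, cfg$input_span_s, 2))
  half <- (cfg$input_span_s - cfg$epoch_s) / 2
  nn <- length(chans$ihr)
  for (e in seq_len(n_ep)) {
    t0 <- (e - 1) * cfg$epoch_s - half
    idx <- pmin(nn, pmax(1L, as.integer(floor(t0) + seq_len(cfg$input_span_s))))
    x[e, , 1] <- chans$ihr[idx]
    x[e, , 2] <- chans$spo2_delayed[idx]
  }
  y <- hypnogram_states(rec$hypnogram)[seq_len(n_ep)]
  list(x = x, y = y)
}

#' Build a labelled training/testing set from simulated nights
#'
#' Generates `n_nights` recordings (seeds `seed + 1 .. seed + n_nights`),
#' runs the preprocessing/feature pipeline, labels windows from ground
#' truth, and returns a night-disjoint train/test split (no window of a
#' test night ever appears in training).
#'
#' @param cfg a [sim_config()], or a list of them cycled across nights (a
#'   configuration grid, e.g. richer event/wake loads for training nights);
#'   per-night seeds are overridden.
#' @param n_nights number of nights (>= 2).
#' @param seed base seed.
#' @param n_test_nights how many nights go to the test split (default 1).
#' @param event_cfg an [event_model_config()].
#' @param sw_cfg a [sleepwake_config()].
#' @return list with `event` (x, y, night), `sleepwake` (x, y, night),
#'   `split` (train/test night ids) and `nights` (per-night pipeline
#'   artifacts: recording, truth, frames, labels).
#' @export
make_training_set <- function(cfg = sim_config(), n_nights = 4, seed = 1L,
                              n_test_nights = 1L,
                              event_cfg = event_model_config(),
                              sw_cfg = sleepwake_config()) {
  stopifnot(n_nights >= 2)
  nights <- vector("list", n_nights)
  ev_x <- list(); ev_y <- character(0); ev_night <- integer(0)
  sw_x <- list(); sw_y <- character(0); sw_night <- integer(0)
  cfgs <- if (inherits(cfg, "sim_config")) list(cfg) else cfg
  for (i in seq_len(n_nights)) {
    cfg_i <- cfgs[[(i - 1L) %% length(cfgs) + 1L]]
    cfg_i$seed <- seed + i
    sim <- generate_recording(cfg_i)
    pf <- pipeline_features(sim$recording)
    labels <- frame_truth_labels(pf$frames, sim$recording$events)
    win <- make_event_windows(pf$frames, labels, event_cfg)
    sww <- sleepwake_windows(sim$recording, sw_cfg)
    ev_x[[i]] <- win$x; ev_y <- c(ev_y, win$y)
    ev_night <- c(ev_night, rep(i, length(win$y)))
    sw_x[[i]] <- sww$x; sw_y <- c(sw_y, sww$y)
    sw_night <- c(sw_night, rep(i, length(sww$y)))
    nights[[i]] <- list(recording = sim$recording, truth = sim$truth,
                        frames = pf$frames, labels = labels,
                        pipeline = pf)
  }
  bind3 <- function(lst) {
    tot <- sum(vapply(lst, function(a) dim(a)[1], 0L))
    out <- array(0, c(tot, dim(lst[[1]])[2], dim(lst[[1]])[3]))
    at <- 0L
    for (a in lst) { out[at + seq_len(dim(a)[1]), , ] <- a; at <- at + dim(a)[1] }
    out
  }
  test_nights <- seq(n_nights - n_test_nights + 1L, n_nights)
  list(event = list(x = bind3(ev_x), y = ev_y, night = ev_night),
       sleepwake = list(x = bind3(sw_x), y = sw_y, night = sw_night),
       split = list(train = setdiff(seq_len(n_nights), test_nights),
                    test = test_nights),
       nights = nights)
}
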