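# End-to-end scoring: preprocess -> features -> classifier -> desaturation
# -> sleep-wake -> fusion -> events -> AHI.

#' Score an overnight recording
#'
#' Runs the full chain on a raw recording: axis selection and filtering,
#' synchrosqueezing envelopes, nine-feature frames, LSTM event
#' probabilities, SpO2 desaturation marks, CNN sleep-wake staging, fusion,
#' event extraction and AHI/severity scoring.
#'
#' @param rec a [recording()].
#' @param event_model a trained `event_model`.
#' @param sw_model a trained `sleepwake_model`, or NULL with
#'   `use_sleepwake = FALSE`.
#' @param use_sleepwake stage sleep/wake with the CNN; when FALSE all
#'   epochs are treated as sleep (TST = recording length).
#' @param use_desat apply the desaturation-based NOR->HYP correction.
#' @param scheme a [window_scheme()].
#' @return list of class `score_result`: `report` (an [ahi_report()]),
#'   `events`, `hypnogram`, `probs`, `step_labels`, `desat`, `frames`.
#' @export
score_recording <- function(rec, event_model, sw_model = NULL,
                            use_sleepwake = TRUE, use_desat = TRUE,
                            scheme = window_scheme()) {
  pf <- pipeline_features(rec, scheme)
  probs <- predict_event_probs(event_model, pf$frames)
  desat <- if (use_desat) detect_desaturation(rec$spo2) else NULL
  hypno <- if (use_sleepwake) {
    if (is.null(sw_model)) stop("use_sleepwake = TRUE needs a sleepwake model",
                                call. = FALSE)
    predict_sleepwake(sw_model, rec)
  } else {
    hypnogram_from_states(rep("sleep", floor(recording_duration(rec) / 30)))
  }
  labels <- fuse(probs, desat, hypno)
  events <- extract_events(labels, step_s = scheme$cw_step_s,
                           t0_s = probs$t_s[1])
  report <- compute_ahi(events, hypno)
  structure(list(report = report, events = events, hypnogram = hypno,
                 probs = probs, step_labels = labels, desat = desat,
                 frames = pf$frames),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
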