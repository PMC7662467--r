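# YAML-backed run configuration: windowing, model hyperparameters,
# simulator settings, paths and the seed, with schema validation.

RUN_CONFIG_KEYS <- c("seed", "windows", "event_model", "sleepwake", "sim",
                     "paths")

#' Default run configuration
#'
#' @return nested list of class `run_config` bundling [window_scheme()],
#'   [event_model_config()], [sleepwake_config()] and [sim_config()]
#'   fields plus `seed` and `paths`.
#' @export
default_run_config <- function() {
  structure(list(seed = 1L,
                 windows = unclass(window_scheme()),
                 event_model = unclass(event_model_config()),
                 sleepwake = unclass(sleepwake_config()),
                 sim = unclass(sim_config()),
                 paths = list()),
            class = "run_config")
}

#' Load and validate a run configuration from YAML
#'
#' Unknown keys (at the top level or inside a known section) are rejected;
#' values present in the file override the defaults.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @param overrides named list applied after the file (CLI flags win).
#' @return validated `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  merge_in <- function(cfg, upd, where = "") {
    for (k in names(upd)) {
      known <- if (where == "") RUN_CONFIG_KEYS else names(cfg)
      if (!k %in% known) {
        stop("unknown config key '", if (where != "") paste0(where, ".") else "",
             k, "'", call. = FALSE)
      }
      if (is.list(cfg[[k]]) && is.list(upd[[k]]) && k != "paths" &&
          !k %in% c("event_rate_per_h", "wake_bouts")) {
        cfg[[k]] <- merge_in(cfg[[k]], upd[[k]], k)
      } else {
        cfg[[k]] <- upd[[k]]
      }
    }
    cfg
  }
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- merge_in(cfg, y)
  }
  cfg <- merge_in(cfg, overrides)
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed))
  w <- cfg$windows
  if (any(unlist(w[c("cw_len_s", "cw_step_s", "pw_len_s", "spo2_seg_s")]) <= 0)) {
    stop("window lengths must be positive", call. = FALSE)
  }
  if (cfg$sim$duration_h <= 0) stop("sim duration must be positive", call. = FALSE)
  invisible(cfg)
}

# rebuild typed configs from a run_config
rc_window_scheme <- function(cfg) do.call(window_scheme, cfg$windows[
  c("cw_len_s", "cw_step_s", "pw_len_s", "spo2_seg_s", "spo2_delay_s")])
rc_event_cfg <- function(cfg) do.call(event_model_config, cfg$event_model)
rc_sw_cfg <- function(cfg) do.call(sleepwake_config, cfg$sleepwake)
rc_sim_cfg <- function(cfg) do.call(sim_config, cfg$sim)

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial rolling hash; avoids extra dependencies
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
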