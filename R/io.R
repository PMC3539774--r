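#' Read syllable annotations from CSV
#'
#' Expects the header `label,onset_s,offset_s` with an optional `f0_hz`
#' column. Intervals must be positive, non-overlapping and time-ordered;
#' validation failures name the offending file line (header is line 1).
#'
#' @param path Path to an annotation CSV.
#' @return Data frame with columns `label`, `onset_s`, `offset_s` and, if
#'   present, `f0_hz`. Zero rows for an empty (header-only) file.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "onset_s", "offset_s")
  if (!all(need %in% names(df)) ||
      !all(names(df) %in% c(need, "f0_hz"))) {
    stop("annotation header must be label,onset_s,offset_s[,f0_hz]; got: ",
         paste(names(df), collapse = ","))
  }
  if (!nrow(df)) return(df)
  bad <- which(df$offset_s <= df$onset_s)
  if (length(bad)) {
    stop("offset <= onset on line ", bad[1] + 1L, " of ", path)
  }
  if (nrow(df) > 1L) {
    unordered <- which(diff(df$onset_s) < 0)
    if (length(unordered)) {
      stop("onsets decrease on line ", unordered[1] + 2L, " of ", path)
    }
    overlap <- which(df$onset_s[-1] < df$offset_s[-nrow(df)])
    if (length(overlap)) {
      stop("overlapping intervals on line ", overlap[1] + 2L, " of ", path)
    }
  }
  df
}

#' Write syllable annotations to CSV
#'
#' @param path Output path.
#' @param annotations Data frame with `label`, `onset_s`, `offset_s` and
#'   optionally `f0_hz`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(path, annotations) {
  keep <- intersect(c("label", "onset_s", "offset_s", "f0_hz"),
                    names(annotations))
  utils::write.csv(annotations[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# one JSON object per event row, NA fields dropped
event_record <- function(row) {
  rec <- list(type = row$type, time_samples = row$time_samples,
              time_s = row$time_s)
  if (!is.na(row$template_id)) rec$template_id <- row$template_id
  if (!is.na(row$correlation)) rec$correlation <- row$correlation
  if (!is.na(row$rms)) rec$rms <- row$rms
  if (!is.na(row$mode)) rec$mode <- row$mode
  rec
}

#' Write an engine event log as JSON lines
#'
#' One JSON object per line, append-friendly. Times are serialized both in
#' samples (authoritative, exact) and seconds (convenience). Records are
#' emitted in non-decreasing time order; simultaneous records (two
#' templates crossing threshold at the same hop) keep the engine's
#' deterministic order.
#'
#' @param events Event-log data frame ([run_stream()] / [engine_feed()]).
#' @param path Output path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  if (nrow(events) && is.unsorted(events$time_samples)) {
    stop("event log must be in non-decreasing time order")
  }
  lines <- vapply(seq_len(nrow(events)), function(i) {
    as.character(jsonlite::toJSON(event_record(events[i, ]),
                                  auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#'
#' @param path Path to a JSON-lines event log.
#' @return Event-log data frame with the standard columns.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- new_events_df(length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i])
    out$type[i] <- rec$type
    out$time_samples[i] <- rec$time_samples
    out$time_s[i] <- rec$time_s
    out$template_id[i] <- rec$template_id %||% NA_character_
    out$correlation[i] <- rec$correlation %||% NA_real_
    out$rms[i] <- rec$rms %||% NA_real_
    out$mode[i] <- rec$mode %||% NA_character_
  }
  out
}

# allowed keys per config section; unknown keys are errors, not warnings
config_schema <- list(
  spectral = c("sample_rate_hz", "fft_size", "hop_ms", "taper",
               "magnitude_scale", "band_hz"),
  engine = c("gate_rms_threshold", "idle_return_rms_threshold",
             "gate_window_ms", "gate_check_every_ms",
             "idle_return_window_ms", "idle_return_check_every_s",
             "refractory_ms", "record_triggered", "templates"),
  feedback = c("mode", "probability", "delay_ms", "pitch_threshold_hz",
               "direction", "sound", "sound_duration_ms", "amplitude",
               "waveform_file", "noise_kind"),
  run = c("seed", "pickup_gain", "target_id", "verbosity"))

check_keys <- function(section, values) {
  unknown <- setdiff(names(values), config_schema[[section]])
  if (length(unknown)) {
    stop("unknown key(s) in [", section, "] config: ",
         paste(unknown, collapse = ", "))
  }
}

#' Read a run configuration from YAML
#'
#' A structured-text config whose field names mirror the constructor
#' arguments of [spectral_params()], [engine_config()] and
#' [feedback_policy()], plus a `run` section (`seed`, `pickup_gain`,
#' `target_id`). Unknown keys are errors. Template files named under
#' `engine.templates` are loaded relative to the config file.
#'
#' @param path Path to a YAML config.
#' @return List with `params`, `config` (engine config, if templates were
#'   given), `policy`, and `run`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(config_schema))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  sp <- y$spectral %||% list()
  check_keys("spectral", sp)
  params <- do.call(spectral_params, sp)
  policy <- NULL
  if (!is.null(y$feedback)) {
    fb <- y$feedback
    check_keys("feedback", fb)
    if (!is.null(fb$waveform_file)) {
      fb$waveform <- read_wav(file.path(dirname(path), fb$waveform_file))$wave
      fb$waveform_file <- NULL
    }
    policy <- do.call(feedback_policy, fb)
  }
  config <- NULL
  if (!is.null(y$engine)) {
    en <- y$engine
    check_keys("engine", en)
    tpl_files <- en$templates
    en$templates <- NULL
    if (!is.null(tpl_files)) {
      tpls <- lapply(tpl_files, function(f) {
        read_template(file.path(dirname(path), f))
      })
      config <- do.call(engine_config,
                        c(list(templates = tpls, params = params), en))
    }
  }
  run <- y$run %||% list()
  check_keys("run", run)
  list(params = params, config = config, policy = policy, run = run)
}

#' Write a run configuration to YAML
#'
#' @param path Output path.
#' @param params A [spectral_params()] (optional).
#' @param engine Named list of engine settings, including a `templates`
#'   vector of template file names (optional).
#' @param feedback Named list of feedback-policy settings (optional).
#' @param run Named list with `seed` etc. (optional).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(path, params = NULL, engine = NULL,
                             feedback = NULL, run = NULL) {
  y <- list()
  if (!is.null(params)) {
    y$spectral <- list(sample_rate_hz = params$sample_rate_hz,
                       fft_size = params$fft_size, hop_ms = params$hop_ms,
                       taper = params$taper,
                       magnitude_scale = params$magnitude_scale)
    if (!is.null(params$band_hz)) y$spectral$band_hz <- params$band_hz
  }
  if (!is.null(engine)) y$engine <- engine
  if (!is.null(feedback)) y$feedback <- feedback
  if (!is.null(run)) y$run <- run
  yaml::write_yaml(y, path)
  invisible(path)
}
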