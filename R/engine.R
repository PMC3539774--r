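#' Root-mean-square amplitude of a window
#'
#' @param x Non-empty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) < 1L) stop("rms of an empty window is undefined")
  sqrt(mean(x * x))
}

#' Calibrate amplitude-gate thresholds from a noise-floor segment
#'
#' The reference apparatus gates spectral processing on input rms but does
#' not publish threshold values; here thresholds are expressed as multiples
#' of the rms of a quiet (noise-floor) reference segment, with hysteresis
#' (trigger > idle-return) so the mode does not oscillate.
#'
#' @param noise Numeric vector of background-noise samples.
#' @param k_trigger Trigger threshold as a multiple of the noise rms.
#' @param k_idle Idle-return threshold as a multiple of the noise rms.
#' @return List with `gate_rms_threshold` and `idle_return_rms_threshold`.
#' @export
calibrate_gate <- function(noise, k_trigger = 3, k_idle = 1.5) {
  stopifnot(length(noise) > 0, k_trigger > k_idle, k_idle > 0)
  r <- rms(noise)
  list(gate_rms_threshold = k_trigger * r,
       idle_return_rms_threshold = k_idle * r)
}

#' Streaming detection engine configuration
#'
#' Fixes every parameter of the two-mode engine: spectral settings, the
#' template bank, the idle-mode amplitude gate (rms of the last
#' `gate_window_ms`, checked every `gate_check_every_ms`), the triggered-mode
#' idle-return check (rms of the last `idle_return_window_ms`, checked every
#' `idle_return_check_every_s`), and the per-template re-detection lockout.
#'
#' @param templates A `song_template` or list of them. All must share the
#'   engine's bin count. Templates are kept ordered by id; simultaneous
#'   threshold crossings are emitted in that order.
#' @param params A [spectral_params()] object.
#' @param gate_rms_threshold Idle-mode trigger threshold (amplitude units);
#'   see [calibrate_gate()].
#' @param idle_return_rms_threshold Triggered-mode release threshold; must
#'   be below `gate_rms_threshold` (hysteresis).
#' @param gate_window_ms,gate_check_every_ms Idle-gate window and period, ms.
#' @param idle_return_window_ms Idle-return rms window, ms.
#' @param idle_return_check_every_s Idle-return check period, seconds.
#' @param refractory_ms Per-template re-detection lockout after each
#'   detection, ms. `NULL` (default) uses each template's own patch span, so
#'   one syllable rendition yields one event rather than one per hop while
#'   the correlation stays above threshold.
#' @param record_triggered Record the audio of each triggered segment.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(templates,
                          params = spectral_params(),
                          gate_rms_threshold,
                          idle_return_rms_threshold,
                          gate_window_ms = 10,
                          gate_check_every_ms = 1,
                          idle_return_window_ms = 200,
                          idle_return_check_every_s = 1,
                          refractory_ms = NULL,
                          record_triggered = TRUE) {
  if (inherits(templates, "song_template")) templates <- list(templates)
  if (!length(templates) || !all(vapply(templates, inherits, TRUE, "song_template"))) {
    stop("templates must be one or more song_template objects")
  }
  ids <- vapply(templates, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("template ids must be unique")
  templates <- templates[order(ids)]
  names(templates) <- sort(ids)
  for (tpl in templates) {
    if (nrow(tpl$patch) != params$n_bins) {
      stop("template ", tpl$id, " bin count does not match engine params")
    }
  }
  stopifnot(is.numeric(gate_rms_threshold), gate_rms_threshold >= 0,
            is.numeric(idle_return_rms_threshold), idle_return_rms_threshold >= 0,
            gate_window_ms > 0, gate_check_every_ms > 0,
            idle_return_window_ms > 0, idle_return_check_every_s > 0,
            record_triggered %in% c(TRUE, FALSE))
  if (!is.null(refractory_ms)) stopifnot(refractory_ms >= 0)
  fs <- params$sample_rate_hz
  ms <- function(x) max(1L, as.integer(round(x * fs / 1000)))
  refr <- vapply(templates, function(tpl) {
    if (is.null(refractory_ms)) {
      as.integer(tpl$n_cols) * params$hop
    } else {
      as.integer(round(refractory_ms * fs / 1000))
    }
  }, integer(1))
  structure(
    list(params = params, templates = templates,
         gate_rms_threshold = gate_rms_threshold,
         idle_return_rms_threshold = idle_return_rms_threshold,
         gate_window = ms(gate_window_ms),
         gate_period = ms(gate_check_every_ms),
         idle_window = ms(idle_return_window_ms),
         idle_period = max(1L, as.integer(round(idle_return_check_every_s * fs))),
         refractory = refr,
         record_triggered = record_triggered),
    class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>", length(x$templates), "template(s):",
      paste(names(x$templates), collapse = ", "), "\n")
  cat("  gate rms >", signif(x$gate_rms_threshold, 4), "| idle-return rms <",
      signif(x$idle_return_rms_threshold, 4), "\n")
  invisible(x)
}

# empty event accumulator entry
new_events_df <- function(n = 0L) {
  data.frame(type = character(n), time_samples = numeric(n),
             time_s = numeric(n), template_id = character(n),
             correlation = numeric(n), rms = numeric(n), mode = character(n),
             stringsAsFactors = FALSE)
}

# shared zero-row log; data.frame() construction is costly and engine_step
# returns an empty log on almost every sample
EMPTY_EVENTS <- new_events_df()

#' Initialize streaming engine state
#'
#' Creates the mutable state driven by [engine_step()] / [engine_feed()]:
#' the raw-sample ring (capacity 2 s of audio), the FFT-column ring
#' (capacity >= 500 columns), mode flags, lockout and per-template
#' refractory clocks, and the event/segment accumulators. The configuration
#' is fixed for the lifetime of the state.
#'
#' @param config An [engine_config()] object.
#' @return An environment of class `engine_state`.
#' @export
engine_init <- function(config) {
  if (!inherits(config, "engine_config")) {
    stop("engine_init() needs an engine_config; got ", class(config)[1])
  }
  p <- config$params
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$mode <- "idle"
  st$n <- 0                                   # total samples pushed
  st$sring <- sample_ring(max(2 * p$sample_rate_hz, 4L * p$fft_size))
  max_cols <- max(vapply(config$templates, function(t) as.integer(t$n_cols),
                         integer(1)))
  st$spring <- spectro_ring(p$n_bins, max(500L, 2L * max_cols))
  st$lockout_until <- 0
  st$refr_until <- stats::setNames(numeric(length(config$templates)),
                                   names(config$templates))
  # precomputed per-template correlation terms (centered patch, norm)
  rows <- band_rows(p)
  st$rows <- if (length(rows) == p$n_bins) NULL else rows
  st$tstats <- lapply(config$templates, function(tpl) {
    v <- as.numeric(if (is.null(st$rows)) tpl$patch else tpl$patch[st$rows, , drop = FALSE])
    vc <- v - mean(v)
    list(id = tpl$id, centered = vc, norm = sqrt(sum(vc * vc)),
         n_cols = tpl$n_cols, threshold = tpl$threshold)
  })
  # flat caches for the hot loop (avoid repeated list traversal per hop)
  st$hop <- p$hop
  st$fft_size <- p$fft_size
  st$taper_vec <- p$taper_vec
  st$n_bins <- p$n_bins
  st$log_scale <- identical(p$magnitude_scale, "log")
  st$next_gate <- config$gate_period
  st$next_hop <- NA_real_
  st$next_idle <- NA_real_
  st$events <- vector("list", 64L)
  st$n_events <- 0L
  st$segments <- list()
  st$seg_open <- FALSE
  st$seg_start <- NA_real_
  st$seg_chunks <- NULL
  class(st) <- "engine_state"
  st
}

#' @export
print.engine_state <- function(x, ...) {
  cat("<engine_state> mode", x$mode, "| samples", x$n, "| events",
      x$n_events, "| segments", length(x$segments) + as.integer(x$seg_open),
      "\n")
  invisible(x)
}

push_event <- function(st, ev) {
  k <- st$n_events + 1L
  if (k > length(st$events)) {
    st$events <- c(st$events, vector("list", length(st$events)))
  }
  st$events[[k]] <- ev
  st$n_events <- k
}

events_as_df <- function(st, from = 1L) {
  idx <- seq.int(from, length.out = max(0L, st$n_events - from + 1L))
  if (!length(idx)) return(EMPTY_EVENTS)
  fs <- st$config$params$sample_rate_hz
  ev <- st$events[idx]
  data.frame(
    type = vapply(ev, `[[`, "", "type"),
    time_samples = vapply(ev, `[[`, 0, "time"),
    time_s = vapply(ev, `[[`, 0, "time") / fs,
    template_id = vapply(ev, function(e) e$template_id %||% NA_character_, ""),
    correlation = vapply(ev, function(e) e$correlation %||% NA_real_, 0),
    rms = vapply(ev, function(e) e$rms %||% NA_real_, 0),
    mode = vapply(ev, function(e) e$mode %||% NA_character_, ""),
    stringsAsFactors = FALSE)
}

# fire whatever checkpoints are due at the current sample count
fire_checkpoints <- function(st) {
  cfg <- st$config
  t <- st$n
  if (st$mode == "idle") {
    if (t == st$next_gate) {
      st$next_gate <- st$next_gate + cfg$gate_period
      if (t >= cfg$gate_window) {
        w <- st$sring$window(cfg$gate_window)
        r <- sqrt(mean(w * w))
        if (r > cfg$gate_rms_threshold) {
          st$mode <- "triggered"
          push_event(st, list(type = "mode_change", time = t, rms = r,
                              mode = "triggered"))
          st$spring$reset()
          hop <- st$hop
          st$next_hop <- (t %/% hop + 1) * hop
          st$next_idle <- (t %/% cfg$idle_period + 1) * cfg$idle_period
          if (cfg$record_triggered) {
            pre <- min(t, st$sring$capacity, cfg$gate_window)
            st$seg_open <- TRUE
            st$seg_start <- t - pre + 1
            st$seg_chunks <- list(st$sring$window(pre))
          }
        }
      }
    }
  } else {
    if (t == st$next_hop) {
      st$next_hop <- st$next_hop + st$hop
      if (t >= st$fft_size) {
        col <- Mod(stats::fft(st$sring$window(st$fft_size) *
                                st$taper_vec))[seq_len(st$n_bins)]
        if (st$log_scale) col <- log1p(col)
        st$spring$push(col, t)
        stored <- min(st$spring$n_pushed, st$spring$capacity)
        tstats <- st$tstats
        for (i in seq_along(tstats)) {
          ts <- tstats[[i]]
          if (stored < ts$n_cols) next
          if (t < st$lockout_until || t < st$refr_until[[i]]) next
          patch <- st$spring$cols(ts$n_cols)
          if (!is.null(st$rows)) patch <- patch[st$rows, , drop = FALSE]
          x <- as.numeric(patch)
          xc <- x - mean(x)
          den <- sqrt(sum(xc * xc)) * ts$norm
          if (den == 0) next  # silent patch: gate territory, never a match
          r <- sum(xc * ts$centered) / den
          if (r >= ts$threshold) {
            push_event(st, list(type = "detection", time = t,
                                template_id = ts$id, correlation = r))
            st$refr_until[[i]] <- t + cfg$refractory[[i]]
          }
        }
      }
    }
    if (t == st$next_idle) {
      st$next_idle <- st$next_idle + cfg$idle_period
      if (t >= cfg$idle_window) {
        w <- st$sring$window(cfg$idle_window)
        r <- sqrt(mean(w * w))
        if (r < cfg$idle_return_rms_threshold) {
          st$mode <- "idle"
          push_event(st, list(type = "mode_change", time = t, rms = r,
                              mode = "idle"))
          close_segment(st, t)
          st$next_gate <- (t %/% cfg$gate_period + 1) * cfg$gate_period
          st$next_hop <- NA_real_
          st$next_idle <- NA_real_
        }
      }
    }
  }
  invisible(st)
}

close_segment <- function(st, end_time) {
  if (!st$seg_open) return(invisible(st))
  samples <- unlist(st$seg_chunks, use.names = FALSE)
  st$segments[[length(st$segments) + 1L]] <-
    list(start = st$seg_start, end = end_time, samples = samples)
  st$seg_open <- FALSE
  st$seg_chunks <- NULL
  invisible(st)
}

#' Feed a chunk of samples through the engine
#'
#' Processes `samples` causally, one checkpoint at a time: while idle, the
#' rms gate is evaluated on its ms grid; while triggered, an FFT column is
#' pushed every hop and each template's correlation against the most recent
#' same-shape patch is tested against its threshold (outside lockout and
#' refractory), and the idle-return rms check runs on its 1 s grid. All
#' grids are global sample grids, so the emitted event log is independent of
#' how the stream is chunked.
#'
#' @param state An [engine_init()] state (mutated in place).
#' @param samples Numeric vector of new samples, arrival order.
#' @return Data frame of the events emitted while processing this chunk
#'   (zero rows if none): columns `type`, `time_samples`, `time_s`,
#'   `template_id`, `correlation`, `rms`, `mode`.
#' @export
engine_feed <- function(state, samples) {
  if (!inherits(state, "engine_state")) stop("state must come from engine_init()")
  samples <- as.numeric(samples)
  ev0 <- state$n_events + 1L
  if (!length(samples)) return(events_as_df(state, ev0))
  cfg <- state$config
  pos <- 0L
  n_new <- length(samples)
  repeat {
    t_next <- if (state$mode == "idle") state$next_gate
              else min(state$next_hop, state$next_idle)
    gap <- t_next - state$n
    if (gap > n_new - pos) {
      if (pos < n_new) {
        chunk <- samples[(pos + 1L):n_new]
        state$sring$push(chunk)
        state$n <- state$n + length(chunk)
        if (state$seg_open) {
          state$seg_chunks[[length(state$seg_chunks) + 1L]] <- chunk
        }
      }
      break
    }
    if (gap > 0) {
      chunk <- samples[(pos + 1L):(pos + gap)]
      state$sring$push(chunk)
      state$n <- state$n + gap
      if (state$seg_open) {
        state$seg_chunks[[length(state$seg_chunks) + 1L]] <- chunk
      }
      pos <- pos + gap
    }
    fire_checkpoints(state)
  }
  events_as_df(state, ev0)
}

#' Advance the engine by a single sample
#'
#' Identical to [engine_feed()] with a length-one chunk; provided as the
#' elementary causal operation. Output depends only on samples already
#' pushed.
#'
#' @param state An [engine_init()] state.
#' @param sample One numeric sample.
#' @return Data frame of events emitted at this sample (usually zero rows).
#' @export
engine_step <- function(state, sample) {
  if (length(sample) != 1L) stop("engine_step() takes exactly one sample")
  engine_feed(state, sample)
}

#' Close any open triggered segment at end of stream
#'
#' @param state An engine state.
#' @return The state, invisibly.
#' @export
engine_finalize <- function(state) {
  close_segment(state, state$n)
  invisible(state)
}

#' Run the engine over a complete recording
#'
#' Batch driver over [engine_feed()]: initializes a fresh state, streams the
#' whole waveform through it, closes the final open segment at end of
#' stream, and returns the full event log and recorded triggered segments.
#' By construction the log is identical to feeding the same samples through
#' [engine_step()] one at a time.
#'
#' @param samples Non-empty numeric waveform.
#' @param config An [engine_config()] object.
#' @return List with `events` (data frame), `segments` (list of
#'   `start`/`end`/`samples`), and the final `state`.
#' @export
run_stream <- function(samples, config) {
  if (!length(samples)) stop("empty input stream")
  state <- engine_init(config)
  events <- engine_feed(state, samples)
  engine_finalize(state)
  list(events = events, segments = state$segments, state = state)
}

#' Detection events from an event log
#'
#' @param events Event-log data frame.
#' @param template_id Optional template id filter.
#' @return The detection rows.
#' @export
detections <- function(events, template_id = NULL) {
  d <- events[events$type == "detection", , drop = FALSE]
  if (!is.null(template_id)) {
    d <- d[d$template_id %in% template_id, , drop = FALSE]
  }
  d
}
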