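#' Contingent-feedback policy
#'
#' Describes whether and how a detection of the target syllable yields
#' acoustic feedback: never (`off`), on every detection (`always`), with a
#' fixed probability per detection (`probabilistic`, reference experiments
#' use p = 0.05 so that almost every song contains at most one playback), or
#' conditional on the estimated syllable pitch falling strictly below or
#' strictly above a threshold (`pitch_conditional`, the escape-conditioning
#' protocol: reference thresholds 3530 Hz, later 3510 Hz).
#'
#' @param mode One of `"off"`, `"always"`, `"probabilistic"`,
#'   `"pitch_conditional"`.
#' @param probability Playback probability per detection, in `[0, 1]`.
#' @param delay_ms Delay from the syllable onset to playback onset, ms
#'   (reference value 40). The syllable onset is recovered from the
#'   detection time by subtracting the template's post-onset extent.
#' @param pitch_threshold_hz Pitch threshold, Hz; required (> 0) in
#'   `pitch_conditional` mode.
#' @param direction `"below"`: feedback when pitch < threshold; `"above"`:
#'   feedback when pitch > threshold. Equality triggers in neither
#'   direction (strict inequalities).
#' @param sound `"white_noise"` or `"stored_waveform"`.
#' @param sound_duration_ms Duration of a white-noise burst, ms.
#' @param amplitude Peak output amplitude scale.
#' @param waveform Stored playback waveform (numeric), required for
#'   `sound = "stored_waveform"`.
#' @param noise_kind White-noise flavour: `"uniform"` (default) or
#'   `"gaussian"`.
#' @return An object of class `feedback_policy`.
#' @export
feedback_policy <- function(mode = c("off", "always", "probabilistic",
                                     "pitch_conditional"),
                            probability = 0.05,
                            delay_ms = 40,
                            pitch_threshold_hz = 3530,
                            direction = c("below", "above"),
                            sound = c("white_noise", "stored_waveform"),
                            sound_duration_ms = 50,
                            amplitude = 0.3,
                            waveform = NULL,
                            noise_kind = c("uniform", "gaussian")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  sound <- match.arg(sound)
  noise_kind <- match.arg(noise_kind)
  stopifnot(probability >= 0, probability <= 1, delay_ms >= 0,
            sound_duration_ms > 0, amplitude >= 0)
  if (mode == "pitch_conditional" &&
      (!is.numeric(pitch_threshold_hz) || pitch_threshold_hz <= 0)) {
    stop("pitch_conditional mode needs pitch_threshold_hz > 0")
  }
  if (sound == "stored_waveform" && is.null(waveform)) {
    stop("stored_waveform sound needs a loaded waveform")
  }
  structure(
    list(mode = mode, probability = probability, delay_ms = delay_ms,
         pitch_threshold_hz = pitch_threshold_hz, direction = direction,
         sound = sound, sound_duration_ms = sound_duration_ms,
         amplitude = amplitude, waveform = waveform,
         noise_kind = noise_kind),
    class = "feedback_policy")
}

#' @export
print.feedback_policy <- function(x, ...) {
  cat("<feedback_policy>", x$mode)
  if (x$mode == "probabilistic") cat(" p =", x$probability)
  if (x$mode == "pitch_conditional") {
    cat(" ", x$direction, x$pitch_threshold_hz, "Hz")
  }
  cat(" | delay", x$delay_ms, "ms |", x$sound, "\n")
  invisible(x)
}

#' FFT-peak pitch contour
#'
#' Estimates the pitch at every hop in a span: at each hop time the
#' magnitude spectrum of the latest `fft_size` samples is computed, and the
#' pitch is the frequency of its largest peak, refined by quadratic
#' (parabolic) interpolation of the log-magnitudes of the peak bin and its
#' two neighbours. At 30.3 kHz / 256 points the raw bin spacing is ~118 Hz;
#' the interpolation supplies the sub-bin precision that makes 20 Hz pitch
#' thresholds meaningful.
#'
#' Hop times lie on the same global hop grid as the engine's spectrogram
#' columns. An all-zero analysis window yields an undefined-pitch marker
#' (`NA`) for that hop, not an error.
#'
#' @param audio Numeric waveform.
#' @param start Reference sample index (typically a detection time); contour
#'   offsets are reported in ms relative to it.
#' @param span_ms Span after `start` to cover, ms.
#' @param params A [spectral_params()] object.
#' @param from_ms Optional span start relative to `start`, ms (default 0).
#' @return An object of class `pitch_estimate`: data frame with
#'   `time_samples`, `offset_ms`, `f_hz` (`NA` where undefined), plus the
#'   reference `start` as an attribute.
#' @export
pitch_contour <- function(audio, start, span_ms, params = spectral_params(),
                          from_ms = 0) {
  fs <- params$sample_rate_hz
  hop <- params$hop
  t_lo <- start + round(from_ms * fs / 1000)
  t_hi <- start + round(span_ms * fs / 1000)
  if (t_hi > length(audio) || t_lo < 1) stop("pitch span outside recording")
  times <- seq.int(ceiling(t_lo / hop) * hop, t_hi, by = hop)
  times <- times[times >= params$fft_size]
  f <- rep(NA_real_, length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    w <- audio[(t - params$fft_size + 1L):t]
    if (all(w == 0)) next
    mag <- Mod(stats::fft(w * params$taper_vec))[seq_len(params$n_bins)]
    k <- which.max(mag)
    if (k == 1L || k == params$n_bins) {
      f[j] <- (k - 1) * fs / params$fft_size
    } else {
      lm <- log(mag[(k - 1L):(k + 1L)] + 1e-300)
      denom <- lm[1] - 2 * lm[2] + lm[3]
      delta <- if (denom == 0) 0 else 0.5 * (lm[1] - lm[3]) / denom
      delta <- max(-0.5, min(0.5, delta))
      f[j] <- (k - 1 + delta) * fs / params$fft_size
    }
  }
  out <- data.frame(time_samples = times,
                    offset_ms = (times - start) / fs * 1000,
                    f_hz = f)
  attr(out, "start") <- start
  class(out) <- c("pitch_estimate", "data.frame")
  out
}

#' Summary pitch of a syllable from its contour
#'
#' The syllable pitch is the minimum defined contour value in a fixed
#' window after the detection time (reference window: 3 to 12 ms).
#'
#' @param contour A [pitch_contour()] result.
#' @param window `c(lo_ms, hi_ms)` window relative to the contour's
#'   reference time.
#' @return Pitch in Hz.
#' @export
syllable_pitch <- function(contour, window = c(3, 12)) {
  stopifnot(inherits(contour, "pitch_estimate"), length(window) == 2L,
            window[1] <= window[2])
  sel <- contour$offset_ms >= window[1] & contour$offset_ms <= window[2] &
    !is.na(contour$f_hz)
  if (!any(sel)) {
    stop("no defined pitch values in the summary window [", window[1], ", ",
         window[2], "] ms")
  }
  min(contour$f_hz[sel])
}

#' Decide whether a detection yields playback
#'
#' Applies the policy contingency. Probabilistic draws use R's current
#' random number generator: one independent uniform draw per call, so
#' decisions are reproducible under a fixed seed and independent across
#' detections.
#'
#' @param policy A [feedback_policy()].
#' @param detection Optional detection event (unused by the decision itself;
#'   accepted for interface symmetry and logging).
#' @param pitch Estimated syllable pitch in Hz; required in
#'   `pitch_conditional` mode.
#' @return `TRUE` if feedback should be played.
#' @export
decide_playback <- function(policy, detection = NULL, pitch = NULL) {
  stopifnot(inherits(policy, "feedback_policy"))
  switch(policy$mode,
    off = FALSE,
    always = TRUE,
    probabilistic = stats::runif(1) < policy$probability,
    pitch_conditional = {
      if (is.null(pitch) || is.na(pitch)) {
        stop("pitch_conditional decision needs a pitch estimate")
      }
      if (policy$direction == "below") pitch < policy$pitch_threshold_hz
      else pitch > policy$pitch_threshold_hz
    })
}

#' Render the feedback sound
#'
#' White noise is drawn fresh on every call (seed-reproducible through R's
#' RNG); a stored waveform is returned scaled by the policy amplitude, so
#' amplitude 1 reproduces the stored samples bit-exactly.
#'
#' @param policy A [feedback_policy()].
#' @param params A [spectral_params()] (for the sample rate).
#' @return Numeric playback waveform.
#' @export
render_feedback <- function(policy, params = spectral_params()) {
  stopifnot(inherits(policy, "feedback_policy"))
  if (policy$sound == "stored_waveform") {
    if (is.null(policy$waveform)) stop("no stored waveform loaded")
    return(policy$waveform * policy$amplitude)
  }
  n <- max(1L, as.integer(round(policy$sound_duration_ms *
                                  params$sample_rate_hz / 1000)))
  if (policy$noise_kind == "uniform") {
    stats::runif(n, -1, 1) * policy$amplitude
  } else {
    stats::rnorm(n) * policy$amplitude / 3  # ~same peak scale as uniform
  }
}

#' Mix scheduled playbacks onto an input waveform
#'
#' Adds each playback waveform, scaled by the microphone pickup gain, onto
#' the input at its scheduled start sample. This simulates the speaker
#' output being picked up by the recording microphone, which is what makes
#' self-trigger lockout necessary. Events extending past the end of the
#' input are truncated with a warning.
#'
#' @param input Numeric waveform.
#' @param playback_events List of events, each with `start` (sample index)
#'   and `waveform`; the `playbacks` data frame of [run_closed_loop()] is
#'   also accepted.
#' @param pickup_gain Non-negative pickup gain.
#' @return The mixed waveform.
#' @export
closed_loop_mix <- function(input, playback_events, pickup_gain = 1) {
  stopifnot(is.numeric(pickup_gain), pickup_gain >= 0)
  out <- as.numeric(input)
  if (is.data.frame(playback_events)) {
    playback_events <- lapply(seq_len(nrow(playback_events)), function(i) {
      list(start = playback_events$start[i],
           waveform = playback_events$waveform[[i]])
    })
  }
  for (ev in playback_events) {
    w <- ev$waveform
    i0 <- as.integer(ev$start)
    i1 <- i0 + length(w) - 1L
    if (i0 > length(out)) {
      warning("playback event at sample ", i0, " lies beyond the waveform end")
      next
    }
    if (i1 > length(out)) {
      warning("playback event truncated at the waveform end")
      w <- w[seq_len(length(out) - i0 + 1L)]
      i1 <- length(out)
    }
    out[i0:i1] <- out[i0:i1] + pickup_gain * w
  }
  out
}

#' Run the full closed detect-and-feedback loop over a recording
#'
#' Streams the recording through the detection engine; every detection of
#' the target template is put through the policy (estimating the syllable
#' pitch first when the policy is pitch-conditional), and a positive
#' decision schedules a playback at `syllable onset + delay_ms`, where the
#' onset is recovered as `detection time - template post-onset extent`.
#' The playback is mixed into the not-yet-processed part of the input at
#' `pickup_gain` (microphone pickup) and the engine is locked out from
#' registering detections until one full patch length after the playback
#' ends, so the system can never trigger on its own output.
#'
#' The stream is processed in blocks no longer than the onset-to-playback
#' margin, so every playback is scheduled before the engine reaches its
#' start sample: the simulation is causal.
#'
#' @param audio Numeric waveform.
#' @param config An [engine_config()].
#' @param policy A [feedback_policy()].
#' @param target_id Template whose detections drive feedback; default the
#'   first template.
#' @param pickup_gain Microphone pickup gain for the playback (0 disables
#'   acoustic mixing but still logs playbacks).
#' @param seed Optional integer seed scoping all probabilistic decisions
#'   and noise rendering in this run.
#' @param pitch_window `c(lo_ms, hi_ms)` summary window for
#'   [syllable_pitch()].
#' @param block Maximum processing block, samples.
#' @return List with `events` (engine log), `playbacks` (data frame:
#'   `cause_time`, `start`, `end`, `template_id`, `pitch_hz`, `played`; one
#'   row per target detection), `output_track` (playback waveform aligned
#'   to the input), `mixed` (input + pickup), and `segments`.
#' @export
run_closed_loop <- function(audio, config, policy,
                            target_id = NULL, pickup_gain = 0.25,
                            seed = NULL, pitch_window = c(3, 12),
                            block = 512L) {
  stopifnot(inherits(config, "engine_config"),
            inherits(policy, "feedback_policy"))
  run <- function() {
    p <- config$params
    fs <- p$sample_rate_hz
    if (is.null(target_id)) target_id <- names(config$templates)[1]
    if (!target_id %in% names(config$templates)) {
      stop("target_id ", target_id, " is not in the template bank")
    }
    tpl <- config$templates[[target_id]]
    delay_samp <- round(policy$delay_ms * fs / 1000)
    patch_span <- tpl$n_cols * p$hop
    # playback can start no earlier than one sample after its cause
    margin <- max(1L, delay_samp - tpl$post_onset_samples)
    blk <- max(1L, min(as.integer(block), margin))
    state <- engine_init(config)
    mixed <- as.numeric(audio)
    out_track <- numeric(length(mixed))
    ev_all <- list()
    pb <- list()
    pos <- 0L
    n <- length(mixed)
    pitch_hi <- max(pitch_window)
    while (pos < n) {
      take <- min(blk, n - pos)
      ev <- engine_feed(state, mixed[(pos + 1L):(pos + take)])
      pos <- pos + take
      ev_all[[length(ev_all) + 1L]] <- ev
      det <- ev[ev$type == "detection" & ev$template_id == target_id, ,
                drop = FALSE]
      for (i in seq_len(nrow(det))) {
        dtime <- det$time_samples[i]
        pitch <- NA_real_
        if (policy$mode == "pitch_conditional") {
          hi <- dtime + round(pitch_hi * fs / 1000)
          pitch <- if (hi <= n) {
            ct <- pitch_contour(mixed, start = dtime, span_ms = pitch_hi,
                                params = p)
            tryCatch(syllable_pitch(ct, window = pitch_window),
                     error = function(e) NA_real_)
          } else NA_real_
        }
        played <- if (policy$mode == "pitch_conditional" && is.na(pitch)) {
          FALSE
        } else {
          decide_playback(policy, pitch = pitch)
        }
        start <- end <- NA_real_
        if (played) {
          w <- render_feedback(policy, p)
          onset <- dtime - tpl$post_onset_samples
          start <- max(onset + delay_samp, dtime + 1)
          end <- start + length(w) - 1
          if (start <= n) {
            i1 <- min(end, n)
            keep <- seq_len(i1 - start + 1L)
            mixed[start:i1] <- mixed[start:i1] + pickup_gain * w[keep]
            out_track[start:i1] <- out_track[start:i1] + w[keep]
          }
          state$lockout_until <- max(state$lockout_until, end + patch_span)
        }
        pb[[length(pb) + 1L]] <- data.frame(
          cause_time = dtime, start = start, end = end,
          template_id = target_id, pitch_hz = pitch, played = played,
          stringsAsFactors = FALSE)
      }
    }
    engine_finalize(state)
    events <- do.call(rbind, c(list(new_events_df()), ev_all))
    playbacks <- if (length(pb)) do.call(rbind, pb) else
      data.frame(cause_time = numeric(0), start = numeric(0),
                 end = numeric(0), template_id = character(0),
                 pitch_hz = numeric(0), played = logical(0))
    list(events = events, playbacks = playbacks, output_track = out_track,
         mixed = mixed, segments = state$segments)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
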