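#' Adaptive virtual bird for long-term pitch-shift experiments
#'
#' A minimal escape-learning agent: it sings songs from its grammar with
#' the target syllable centred on its current mean fundamental, and after
#' every rendition that earned (aversive) feedback it moves the mean a
#' fixed step away from the feedback region -- up when feedback targets
#' pitches below the threshold, down when above. The rule is deliberately
#' simple: it reproduces the phenomenon (gradual pitch drift that makes
#' feedback rarer) without claiming to model the learning mechanism, and
#' exists to exercise the closed detection-feedback loop end to end.
#'
#' @param grammar A [song_grammar()]; defaults to [agent_grammar()].
#' @param target Label of the conditioned syllable.
#' @param mean_f0 Starting mean fundamental of the target syllable, Hz.
#' @param learning_rate Pitch step per fed-back rendition, Hz.
#' @param day_length Songs sung per simulated day.
#' @return An object of class `bird_agent`.
#' @export
bird_agent <- function(grammar = agent_grammar(), target = "a",
                       mean_f0 = 3460, learning_rate = 0.1,
                       day_length = 200) {
  stopifnot(inherits(grammar, "song_grammar"),
            target %in% names(grammar$syllables),
            mean_f0 > 0, learning_rate >= 0, day_length >= 1)
  structure(list(grammar = grammar, target = target, mean_f0 = mean_f0,
                 learning_rate = learning_rate,
                 day_length = as.integer(day_length)),
            class = "bird_agent")
}

#' @export
print.bird_agent <- function(x, ...) {
  cat("<bird_agent> target", x$target, "| mean f0", round(x$mean_f0, 1),
      "Hz | step", x$learning_rate, "Hz |", x$day_length, "songs/day\n")
  invisible(x)
}

#' Simulate one day of closed-loop singing
#'
#' The agent sings `day_length` songs; each one runs through the full
#' detect -> pitch-estimate -> feedback loop ([run_closed_loop()]). After
#' each fed-back rendition the agent's mean fundamental moves
#' `learning_rate` Hz away from the feedback region. Renditions the engine
#' misses produce no pitch estimate and no update.
#'
#' @param agent A [bird_agent()].
#' @param policy A `pitch_conditional` [feedback_policy()].
#' @param config An [engine_config()] whose bank contains a template for
#'   the agent's target syllable.
#' @param params A [spectral_params()].
#' @param pickup_gain Microphone pickup gain for playback mixing.
#' @return List with `agent` (updated), `renditions` (data frame: `song`,
#'   `f0_true`, `pitch_hz`, `detected`, `fed_back`), `mean_pitch`,
#'   `sem_pitch`, `n`, and `n_feedback`.
#' @export
agent_day <- function(agent, policy, config, params = spectral_params(),
                      pickup_gain = 0.25) {
  stopifnot(inherits(agent, "bird_agent"),
            inherits(policy, "feedback_policy"))
  if (policy$mode != "pitch_conditional") {
    stop("agent_day() expects a pitch_conditional feedback policy")
  }
  step_dir <- if (policy$direction == "below") +1 else -1
  rows <- vector("list", agent$day_length)
  for (s in seq_len(agent$day_length)) {
    ov <- stats::setNames(agent$mean_f0, agent$target)
    song <- synth_song(agent$grammar, params, f0_mean_override = ov)
    res <- run_closed_loop(song$wave, config, policy,
                           target_id = agent$target,
                           pickup_gain = pickup_gain)
    f0_true <- song$annotations$f0_hz[song$annotations$label == agent$target][1]
    pb <- res$playbacks
    detected <- nrow(pb) > 0
    pitch <- if (detected) pb$pitch_hz[1] else NA_real_
    fed <- detected && isTRUE(pb$played[1])
    if (fed) {
      agent$mean_f0 <- agent$mean_f0 + step_dir * agent$learning_rate
    }
    rows[[s]] <- data.frame(song = s, f0_true = f0_true, pitch_hz = pitch,
                            detected = detected, fed_back = fed,
                            stringsAsFactors = FALSE)
  }
  renditions <- do.call(rbind, rows)
  ok <- !is.na(renditions$pitch_hz)
  n <- sum(ok)
  mp <- if (n) mean(renditions$pitch_hz[ok]) else NA_real_
  sem <- if (n > 1) stats::sd(renditions$pitch_hz[ok]) / sqrt(n) else 0
  list(agent = agent, renditions = renditions, mean_pitch = mp,
       sem_pitch = sem, n = n, n_feedback = sum(renditions$fed_back))
}

#' Run a multi-phase pitch-conditioning experiment
#'
#' Reproduces the shape of the classic protocol: consecutive phases of
#' pitch-contingent white-noise feedback, each with its own direction and
#' threshold (e.g. 6 days below 3530 Hz, 6 days above 3530 Hz, 6 days
#' below 3510 Hz). The detection template is built once, at the start,
#' from a clean reference rendition at the agent's initial mean pitch.
#'
#' @param agent A [bird_agent()].
#' @param phases Data frame with columns `days`, `direction`
#'   (`"below"`/`"above"`), `threshold_hz`.
#' @param params A [spectral_params()].
#' @param seed Integer seed for the whole experiment.
#' @param template_threshold Correlation threshold for the target template.
#'   The default is calibrated slightly below the single-syllable optimum
#'   so the template keeps catching renditions as the mean pitch drifts
#'   across the conditioning range (the reference procedure likewise tuned
#'   thresholds on a calibration set before fixing them).
#' @param pickup_gain Pickup gain for playback mixing.
#' @param policy_base Optional [feedback_policy()] supplying the playback
#'   sound parameters; its mode/direction/threshold are overridden per
#'   phase.
#' @return List with `renditions` (data frame incl. `day`, `phase`),
#'   `daily` ([daily_pitch_summary()] output with phase info), `trajectory`
#'   (agent mean f0 at the end of each day) and the final `agent`.
#' @export
run_pitch_experiment <- function(agent, phases, params = spectral_params(),
                                 seed = 1, template_threshold = 0.65,
                                 pickup_gain = 0.25, policy_base = NULL) {
  stopifnot(is.data.frame(phases),
            all(c("days", "direction", "threshold_hz") %in% names(phases)))
  withr::with_seed(seed, {
    # template from a clean pre-experiment reference recording (grammar means)
    ref <- reference_song(agent$grammar, params)
    idx <- which(ref$annotations$label == agent$target)[1]
    tpl <- build_template(ref$wave, onset_s = ref$annotations$onset_s[idx],
                          duration_ms = 20, pre_roll_ms = 8, params = params,
                          threshold = template_threshold, id = agent$target,
                          source = "reference_song")
    config <- engine_config_for_grammar(tpl, agent$grammar, params)
    day_no <- 0L
    rend <- list()
    traj <- list()
    for (ph in seq_len(nrow(phases))) {
      policy <- feedback_policy(
        mode = "pitch_conditional",
        direction = phases$direction[ph],
        pitch_threshold_hz = phases$threshold_hz[ph],
        delay_ms = if (is.null(policy_base)) 40 else policy_base$delay_ms,
        sound = "white_noise",
        sound_duration_ms = if (is.null(policy_base)) 50 else
          policy_base$sound_duration_ms,
        amplitude = if (is.null(policy_base)) 0.3 else policy_base$amplitude)
      for (d in seq_len(phases$days[ph])) {
        day_no <- day_no + 1L
        day <- agent_day(agent, policy, config, params,
                         pickup_gain = pickup_gain)
        agent <- day$agent
        r <- day$renditions
        r$day <- day_no
        r$phase <- ph
        rend[[day_no]] <- r
        traj[[day_no]] <- data.frame(day = day_no, phase = ph,
                                     direction = phases$direction[ph],
                                     threshold_hz = phases$threshold_hz[ph],
                                     mean_f0 = agent$mean_f0,
                                     n_feedback = day$n_feedback)
      }
    }
    renditions <- do.call(rbind, rend)
    trajectory <- do.call(rbind, traj)
    ok <- !is.na(renditions$pitch_hz)
    daily <- daily_pitch_summary(renditions$day[ok], renditions$pitch_hz[ok])
    daily <- merge(daily, trajectory[, c("day", "phase", "direction",
                                         "threshold_hz")], by = "day")
    list(renditions = renditions, daily = daily, trajectory = trajectory,
         agent = agent)
  })
}
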