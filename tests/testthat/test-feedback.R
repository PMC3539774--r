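test_that("pitch contour tracks a pure tone within 5 Hz", {
  params <- fix_params()
  fs <- params$sample_rate_hz
  tone <- sin(2 * pi * 3400 * (0:(fs %/% 2)) / fs)
  ct <- pitch_contour(tone, start = 1000, span_ms = 30, params = params)
  expect_true(all(!is.na(ct$f_hz)))
  expect_true(all(abs(ct$f_hz - 3400) < 5))
})

test_that("silence yields undefined-pitch markers, not errors", {
  params <- fix_params()
  ct <- pitch_contour(numeric(20000), start = 5000, span_ms = 20,
                      params = params)
  expect_true(all(is.na(ct$f_hz)))
  expect_error(syllable_pitch(ct), "no defined pitch")
})

test_that("pitch contour recovers the generator's programmed f0", {
  params <- fix_params()
  fs <- params$sample_rate_hz
  spec <- fix_grammar()$syllables$a
  withr::local_seed(41)
  for (f0 in c(3420, 3500, 3575)) {
    w <- c(numeric(2000), synth_syllable(spec, params, f0_override = f0),
           numeric(500))
    # mimic a detection 20 ms into the syllable, then window 3-12 ms later
    det <- 2000 + round(0.020 * fs)
    ct <- pitch_contour(w, start = det, span_ms = 12, params = params,
                        from_ms = 3)
    expect_true(all(abs(ct$f_hz - f0) < 10))
    expect_lt(abs(syllable_pitch(ct) - f0), 10)
  }
})

test_that("syllable pitch is the minimum defined contour value in-window", {
  mk_contour <- function(offsets_ms, values) {
    out <- data.frame(time_samples = offsets_ms * 30.3,
                      offset_ms = offsets_ms, f_hz = values)
    class(out) <- c("pitch_estimate", "data.frame")
    out
  }
  ct <- mk_contour(c(4, 8, 11), c(3550, 3500, 3560))
  expect_identical(syllable_pitch(ct), 3500)
  expect_identical(syllable_pitch(mk_contour(5, 3467)), 3467)
  withr::local_seed(42)
  for (i in 1:50) {
    off <- sort(stats::runif(12, 0, 20))
    val <- stats::runif(12, 3000, 4000)
    val[sample(12, 3)] <- NA
    ct <- mk_contour(off, val)
    sel <- off >= 3 & off <= 12 & !is.na(val)
    if (any(sel)) {
      expect_identical(syllable_pitch(ct), min(val[sel]))
    } else {
      expect_error(syllable_pitch(ct), "no defined pitch")
    }
  }
})

test_that("playback decisions follow the policy contingencies", {
  expect_false(decide_playback(feedback_policy("off")))
  expect_true(decide_playback(feedback_policy("always")))
  expect_true(decide_playback(feedback_policy("probabilistic",
                                              probability = 1)))
  pol <- feedback_policy("pitch_conditional", direction = "below",
                         pitch_threshold_hz = 3530)
  expect_true(decide_playback(pol, pitch = 3400))
  expect_false(decide_playback(pol, pitch = 3600))
  expect_error(decide_playback(pol), "needs a pitch")
})

test_that("probabilistic acceptance rate matches p = 0.05", {
  pol <- feedback_policy("probabilistic", probability = 0.05)
  n <- 20000
  hits <- withr::with_seed(43, sum(vapply(seq_len(n), function(i) {
    decide_playback(pol)
  }, TRUE)))
  sd4 <- 4 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(hits / n - 0.05), sd4)
})

test_that("strict threshold inequalities partition renditions exactly", {
  below <- feedback_policy("pitch_conditional", direction = "below",
                           pitch_threshold_hz = 3530)
  above <- feedback_policy("pitch_conditional", direction = "above",
                           pitch_threshold_hz = 3530)
  withr::local_seed(44)
  pitches <- c(stats::runif(200, 3300, 3700), 3530)
  d_below <- vapply(pitches, function(p) decide_playback(below, pitch = p),
                    TRUE)
  d_above <- vapply(pitches, function(p) decide_playback(above, pitch = p),
                    TRUE)
  at_thr <- pitches == 3530
  expect_true(all(xor(d_below[!at_thr], d_above[!at_thr])))
  expect_false(any(d_below[at_thr]) || any(d_above[at_thr]))
})

test_that("rendered feedback has the configured shape and scale", {
  params <- fix_params()
  syl <- synth_syllable(fix_grammar()$syllables$b, params)
  pol <- feedback_policy("always", sound = "stored_waveform", waveform = syl,
                         amplitude = 1)
  expect_identical(render_feedback(pol, params), syl)
  wn <- feedback_policy("always", sound = "white_noise",
                        sound_duration_ms = 1000, amplitude = 0.4)
  w1 <- withr::with_seed(45, render_feedback(wn, params))
  w2 <- withr::with_seed(45, render_feedback(wn, params))
  expect_identical(w1, w2)
  # uniform noise rms = amplitude / sqrt(3)
  expect_lt(abs(rms(w1) - 0.4 / sqrt(3)) / (0.4 / sqrt(3)), 0.02)
})

test_that("closed-loop mixing adds playback only where scheduled", {
  input <- sin(2 * pi * 500 * (0:9999) / 30300)
  ev <- list(list(start = 2001, waveform = rep(0.25, 300)))
  expect_identical(closed_loop_mix(input, ev, pickup_gain = 0), input)
  mixed <- closed_loop_mix(input, ev, pickup_gain = 1)
  diffv <- mixed - input
  expect_equal(diffv[2001:2300], rep(0.25, 300), tolerance = 1e-12)
  expect_identical(diffv[-(2001:2300)], numeric(9700))
  expect_warning(closed_loop_mix(input,
                                 list(list(start = 9900,
                                           waveform = rep(0.1, 500)))),
                 "truncated")
})

test_that("playback is scheduled at syllable onset + delay", {
  params <- fix_params()
  fs <- params$sample_rate_hz
  cfg <- engine_config_for_grammar(fix_templates()["a"], fix_grammar(),
                                   params)
  tpl <- fix_templates()$a
  song <- synth_song(fix_grammar(), params, seed = 401)
  pol <- feedback_policy("always", delay_ms = 40, sound = "white_noise")
  res <- run_closed_loop(song$wave, cfg, pol, seed = 402)
  pb <- res$playbacks[res$playbacks$played, ]
  expect_gt(nrow(pb), 0)
  onset <- pb$cause_time - tpl$post_onset_samples
  expect_identical(pb$start, onset + round(40 * fs / 1000))
  expect_true(all(pb$start > pb$cause_time))
})

test_that("no detections occur during playback at any pickup gain", {
  params <- fix_params()
  cfg <- engine_config_for_grammar(fix_templates(), fix_grammar(), params)
  ref <- fix_ref_song()
  ann <- ref$annotations
  i <- which(ann$label == "a")[1]
  fs <- params$sample_rate_hz
  syl_a <- ref$wave[round(ann$onset_s[i] * fs):round(ann$offset_s[i] * fs)]
  # playing back the target syllable itself is the worst case for
  # self-triggering
  pol <- feedback_policy("always", sound = "stored_waveform",
                         waveform = syl_a, amplitude = 1)
  for (gain in c(0.1, 1.0)) {
    song <- synth_song(fix_grammar(), params, seed = 403)
    res <- run_closed_loop(song$wave, cfg, pol, target_id = "a",
                           pickup_gain = gain, seed = 404)
    pb <- res$playbacks[res$playbacks$played, ]
    d <- detections(res$events)
    for (k in seq_len(nrow(pb))) {
      expect_identical(sum(d$time_samples >= pb$start[k] &
                             d$time_samples <= pb$end[k]), 0L)
    }
    # and the output track is the rendered playback at its offsets
    expect_equal(res$mixed - song$wave, gain * res$output_track,
                 tolerance = 1e-12)
  }
})
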