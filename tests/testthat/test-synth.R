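test_that("syllable rendering respects duration, pitch and aliasing limits", {
  params <- fix_params()
  spec <- syllable_spec("x", "harmonic_stack", f0_hz = 3500,
                        duration_ms = 40)
  w <- synth_syllable(spec, params)
  expect_lte(abs(length(w) - 1212), 1)
  # dominant FFT peak of the whole syllable within 15 Hz of programmed f0
  mag <- Mod(stats::fft(w))[1:(length(w) %/% 2)]
  f_peak <- (which.max(mag) - 1) * params$sample_rate_hz / length(w)
  expect_lt(abs(f_peak - 3500), 15)
  too_high <- syllable_spec("y", "harmonic_stack", f0_hz = 6000,
                            n_harmonics = 3)
  expect_error(synth_syllable(too_high, params), "Nyquist")
})

test_that("sweep instantaneous frequency decreases monotonically", {
  params <- fix_params()
  spec <- syllable_spec("s", "sweep", f0_hz = 6000, f0_end_hz = 4000,
                        duration_ms = 60, attack_ms = 2, decay_ms = 2)
  pad <- numeric(1500)
  w <- c(pad, synth_syllable(spec, params), pad)
  ct <- pitch_contour(w, start = length(pad) + 400, span_ms = 40,
                      params = params)
  f <- ct$f_hz[!is.na(ct$f_hz)]
  expect_gt(length(f), 20)
  expect_true(all(diff(f) < 0))
  expect_true(all(f < 6100 & f > 3900))
})

test_that("song synthesis is deterministic under a fixed seed", {
  g <- fix_grammar()
  s1 <- synth_song(g, fix_params(), seed = 501)
  s2 <- synth_song(g, fix_params(), seed = 501)
  expect_identical(s1$wave, s2$wave)
  expect_identical(s1$annotations, s2$annotations)
})

test_that("annotations exactly describe the emitted syllable intervals", {
  params <- fix_params()
  fs <- params$sample_rate_hz
  g <- fix_grammar()
  song <- synth_song(g, params, seed = 502)
  ann <- song$annotations
  expect_false(is.unsorted(ann$onset_s))
  expect_true(all(ann$offset_s > ann$onset_s))
  expect_true(all(ann$onset_s[-1] >= ann$offset_s[-nrow(ann)]))
  for (i in seq_len(nrow(ann))) {
    spec <- g$syllables[[ann$label[i]]]
    n_expected <- round(spec$duration_ms * fs / 1000)
    expect_lte(abs(round((ann$offset_s[i] - ann$onset_s[i]) * fs) -
                     n_expected), 1)
  }
  # each annotated interval carries syllable energy well above the gaps
  for (i in seq_len(nrow(ann))) {
    seg <- song$wave[round(ann$onset_s[i] * fs + 1):round(ann$offset_s[i] * fs)]
    expect_gt(rms(seg), 10 * rms(noise_floor_segment(g, params)))
  }
})

test_that("empirical transition frequencies match the grammar", {
  g <- fix_grammar()
  n_songs <- 500
  seqs <- withr::with_seed(503, {
    replicate(n_songs, paste(songtrigger:::draw_sequence(g), collapse = ""),
              simplify = TRUE)
  })
  count_after <- function(lab) {
    nxt <- unlist(lapply(strsplit(seqs, ""), function(s) {
      i <- which(s == lab)
      out <- character(0)
      for (j in i) out <- c(out, if (j < length(s)) s[j + 1] else "end")
      out
    }))
    table(nxt)
  }
  for (lab in c("c", "d")) {
    row <- g$transitions[[lab]]
    obs <- count_after(lab)
    n <- sum(obs)
    for (nx in names(row)) {
      p <- row[[nx]]
      se <- sqrt(p * (1 - p) / n)
      obs_p <- if (nx %in% names(obs)) obs[[nx]] / n else 0
      expect_lt(abs(obs_p - p), 3 * se + 1e-9)
    }
  }
})

test_that("zero-jitter songs are recovered at the annotated times", {
  params <- fix_params()
  g <- zero_jitter(fix_grammar())
  cfg <- fix_config()
  tpl <- fix_templates()$a
  songs <- synth_corpus(g, 5, params, seed = 504)
  for (s in songs) {
    det <- det_table(detections(run_stream(s$wave, cfg)$events, "a"))
    ann <- s$annotations[s$annotations$label == "a", ]
    expect_identical(nrow(det), nrow(ann))
    expected <- round(ann$onset_s * params$sample_rate_hz) +
      tpl$post_onset_samples
    # the engine reports the first threshold crossing, which precedes the
    # best alignment by a few hops while the correlation is still rising;
    # it must stay within the evaluation tolerance of the expected time
    expect_true(all(abs(det$time_samples - expected) <=
                      round(0.010 * params$sample_rate_hz)))
    # the peak of the offline correlation scan pinpoints the annotated
    # time to within one hop
    sg <- oracle_spectrogram(s$wave, params)
    for (e in expected) {
      near <- which(abs(sg$times - e) <= 15 * params$hop)
      rs <- vapply(near, function(j) {
        stats::cor(as.numeric(sg$mags[, (j - tpl$n_cols + 1):j]),
                   as.numeric(tpl$patch))
      }, 0)
      t_peak <- sg$times[near[which.max(rs)]]
      expect_lte(abs(t_peak - e), params$hop)
    }
  }
})

test_that("corpus generation writes a faithful, regenerable manifest", {
  params <- fix_params()
  g <- fix_grammar()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  s1 <- synth_corpus(g, 3, params, seed = 505, dir = dir1)
  s2 <- synth_corpus(g, 3, params, seed = 505, dir = dir2)
  m1 <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  expect_identical(m1, m2)
  expect_identical(m1$seed, 505L)
  expect_identical(m1$grammar_hash, m2$grammar_hash)
  # audio files round-trip the generated waves bit-exactly
  w <- read_wav(file.path(dir1, "song_001.wav"))
  expect_identical(w$wave, s1[[1]]$wave)
  ann <- read_annotations(file.path(dir1, "song_001.csv"))
  expect_equal(ann$onset_s, s1[[1]]$annotations$onset_s, tolerance = 1e-9)
})

test_that("a non-learning agent never changes its pitch", {
  params <- fix_params()
  ag <- bird_agent(day_length = 3, learning_rate = 0)
  pol <- feedback_policy("pitch_conditional", direction = "below",
                         pitch_threshold_hz = 3530)
  ref <- reference_song(ag$grammar, params)
  tpl <- build_templates_from_song(ref, "a", params, threshold = 0.65)
  cfg <- engine_config_for_grammar(tpl, ag$grammar, params)
  day <- withr::with_seed(506, agent_day(ag, pol, cfg, params))
  expect_identical(day$agent$mean_f0, ag$mean_f0)
  expect_gt(day$n_feedback, 0)
})

test_that("escape conditioning drifts pitch away from the feedback region", {
  params <- fix_params()
  ag <- bird_agent(day_length = 25, learning_rate = 1.5)
  phases <- data.frame(days = c(2, 2),
                       direction = c("below", "above"),
                       threshold_hz = c(3530, 3530))
  ex <- run_pitch_experiment(ag, phases, params, seed = 507)
  traj <- ex$trajectory
  # upward drift while feedback targets low pitches, then reversal
  expect_gt(traj$mean_f0[2], traj$mean_f0[1])
  expect_lt(traj$mean_f0[4], traj$mean_f0[3])
  expect_true(all(ex$trajectory$n_feedback > 0))
  # daily summaries reproduce the renditions they aggregate
  ok <- !is.na(ex$renditions$pitch_hz)
  d1 <- ex$renditions$pitch_hz[ok & ex$renditions$day == 1]
  expect_equal(ex$daily$mean_hz[ex$daily$day == 1], mean(d1))
  expect_equal(ex$daily$sem_hz[ex$daily$day == 1],
               stats::sd(d1) / sqrt(length(d1)))
})
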