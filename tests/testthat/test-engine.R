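test_that("rms matches its closed form and direct oracle", {
  expect_identical(rms(numeric(100)), 0)
  expect_identical(rms(rep(-0.3, 50)), 0.3)
  expect_error(rms(numeric(0)), "empty")
  withr::local_seed(21)
  for (i in 1:50) {
    x <- stats::rnorm(sample(2:500, 1))
    expect_equal(rms(x), sqrt(sum(x^2) / length(x)), tolerance = 1e-12)
  }
})

test_that("silence produces no events and no mode changes", {
  cfg <- fix_config()
  res <- run_stream(numeric(5 * 30300), cfg)
  expect_identical(nrow(res$events), 0L)
  expect_identical(res$state$mode, "idle")
  expect_length(res$segments, 0)
})

test_that("a constant tone triggers at the first gate check above threshold", {
  cfg <- fix_config()
  fs <- fix_params()$sample_rate_hz
  tone <- 0.2 * sin(2 * pi * 1000 * (0:(fs / 2)) / fs)
  res <- run_stream(tone, cfg)
  trans <- res$events[res$events$type == "mode_change", ]
  expect_identical(nrow(trans), 1L)
  expect_identical(trans$mode, "triggered")
  # oracle: earliest multiple of the gate period whose trailing-window rms
  # exceeds threshold
  checks <- seq(cfg$gate_period, length(tone), by = cfg$gate_period)
  checks <- checks[checks >= cfg$gate_window]
  ok <- vapply(checks, function(t) {
    rms(tone[(t - cfg$gate_window + 1):t]) > cfg$gate_rms_threshold
  }, TRUE)
  expect_identical(trans$time_samples, as.numeric(checks[which(ok)[1]]))
})

test_that("one embedded target syllable yields one detection at oracle time", {
  params <- fix_params()
  cfg <- fix_config()
  song <- synth_song(fix_grammar(), params, seed = 301)
  res <- run_stream(song$wave, cfg)
  det_a <- det_table(res$events)
  det_a <- det_a[det_a$template_id == "a", ]
  n_a <- sum(song$annotations$label == "a")
  expect_identical(nrow(det_a), n_a)
  oracle <- oracle_scan(song$wave, fix_templates(), params)
  oracle_a <- oracle[oracle$template_id == "a", ]
  expect_identical(nrow(oracle_a), n_a)
  expect_true(all(abs(det_a$time_samples - oracle_a$time_samples) <=
                    params$hop))
})

test_that("event logs are invariant to stream chunking", {
  cfg <- fix_config()
  song <- synth_song(fix_grammar(), fix_params(), seed = 302)
  wave <- song$wave
  ref <- run_stream(wave, cfg)$events
  rownames(ref) <- NULL
  feed_in_chunks <- function(sizes) {
    st <- engine_init(cfg)
    pos <- 0
    acc <- list()
    i <- 1
    while (pos < length(wave)) {
      b <- min(sizes[(i - 1) %% length(sizes) + 1], length(wave) - pos)
      acc[[length(acc) + 1]] <- engine_feed(st, wave[(pos + 1):(pos + b)])
      pos <- pos + b
      i <- i + 1
    }
    out <- do.call(rbind, acc)
    rownames(out) <- NULL
    out
  }
  expect_identical(feed_in_chunks(7), ref)
  expect_identical(feed_in_chunks(4096), ref)
  withr::local_seed(303)
  expect_identical(feed_in_chunks(sample(c(1, 7, 100, 4096), 60,
                                         replace = TRUE)), ref)
  # per-sample stepping over a prefix long enough to contain the first
  # detection
  cut <- 11000
  st <- engine_init(cfg)
  acc <- lapply(wave[1:cut], function(s) engine_step(st, s))
  step_events <- do.call(rbind, acc)
  rownames(step_events) <- NULL
  expect_identical(step_events, ref[ref$time_samples <= cut, ])
})

test_that("truncating the stream never changes past events (causality)", {
  cfg <- fix_config()
  song <- synth_song(fix_grammar(), fix_params(), seed = 304)
  full <- run_stream(song$wave, cfg)$events
  for (cut in c(7500, 9000, 12000)) {
    part <- run_stream(song$wave[1:cut], cfg)$events
    expect_identical(part[part$time_samples <= cut, ],
                     full[full$time_samples <= cut, ])
  }
})

test_that("each template's events are unchanged by the other's presence", {
  params <- fix_params()
  tpls <- fix_templates()
  g <- fix_grammar()
  song <- synth_song(g, params, seed = 305)
  both <- run_stream(song$wave,
                     engine_config_for_grammar(tpls, g, params))$events
  for (id in c("a", "c")) {
    single <- run_stream(song$wave,
                         engine_config_for_grammar(tpls[[id]], g,
                                                   params))$events
    expect_identical(det_table(detections(single, id)),
                     det_table(detections(both, id)))
  }
})

test_that("refractory emits one event per syllable rendition", {
  # without a refractory the correlation stays above threshold for several
  # consecutive hops; the default (one patch span) collapses them to one
  params <- fix_params()
  g <- fix_grammar()
  song <- synth_song(g, params, seed = 306)
  cfg0 <- engine_config_for_grammar(fix_templates()["a"], g, params,
                                    refractory_ms = 0)
  cfg1 <- engine_config_for_grammar(fix_templates()["a"], g, params)
  n_truth <- sum(song$annotations$label == "a")
  expect_gt(nrow(detections(run_stream(song$wave, cfg0)$events)), n_truth)
  expect_identical(nrow(detections(run_stream(song$wave, cfg1)$events)),
                   n_truth)
})

test_that("the engine returns to idle after sustained silence", {
  params <- fix_params()
  g <- fix_grammar()
  cfg <- fix_config()
  song <- synth_song(g, params, seed = 307)
  fs <- params$sample_rate_hz
  wave <- c(song$wave, numeric(2 * fs))   # 2 s of dead silence
  res <- run_stream(wave, cfg)
  trans <- res$events[res$events$type == "mode_change", ]
  expect_identical(trans$mode[nrow(trans)], "idle")
  # the triggered segment was closed and contains every detection
  expect_length(res$segments, 1)
  seg <- res$segments[[1]]
  d <- detections(res$events)
  expect_true(all(d$time_samples >= seg$start & d$time_samples <= seg$end))
  expect_identical(length(seg$samples), as.integer(seg$end - seg$start + 1))
})

test_that("identical input and config give bit-identical logs", {
  cfg <- fix_config()
  song <- synth_song(fix_grammar(), fix_params(), seed = 308)
  e1 <- run_stream(song$wave, cfg)$events
  e2 <- run_stream(song$wave, cfg)$events
  expect_identical(e1, e2)
})

test_that("configuration validation rejects nonsense", {
  tpl <- fix_templates()$a
  expect_error(engine_config(list(), gate_rms_threshold = 1,
                             idle_return_rms_threshold = 0.5),
               "song_template")
  expect_error(engine_config(tpl, gate_rms_threshold = -1,
                             idle_return_rms_threshold = 0.5))
  expect_error(engine_init("not a config"), "engine_config")
  expect_error(run_stream(numeric(0), fix_config()), "empty")
  expect_error(engine_step(engine_init(fix_config()), c(1, 2)),
               "exactly one sample")
})
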