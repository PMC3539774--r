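#' Specification of one syllable type
#'
#' Synthetic Bengalese-finch-like syllables come in two flavours: harmonic
#' stacks (a fundamental plus harmonics at fixed frequency) and frequency
#' sweeps (linear chirps). Durations of 20-100 ms with a short linear
#' attack/decay envelope emulate the natural elements; the default 40 ms
#' matches a typical target syllable.
#'
#' @param label Single-character-ish syllable label.
#' @param kind `"harmonic_stack"` or `"sweep"`.
#' @param f0_hz Fundamental frequency, Hz.
#' @param f0_end_hz Sweep end frequency, Hz (sweeps only; the start is
#'   `f0_hz`).
#' @param n_harmonics Number of harmonics (including the fundamental).
#' @param harmonic_amps Relative harmonic amplitudes; default `1/h`.
#' @param duration_ms Syllable duration, ms.
#' @param attack_ms,decay_ms Linear envelope ramps, ms.
#' @param amplitude Peak amplitude after normalization.
#' @return An object of class `syllable_spec`.
#' @export
syllable_spec <- function(label, kind = c("harmonic_stack", "sweep"),
                          f0_hz, f0_end_hz = NULL, n_harmonics = 1,
                          harmonic_amps = NULL, duration_ms = 40,
                          attack_ms = 5, decay_ms = 5, amplitude = 0.9) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            f0_hz > 0, duration_ms > 0, n_harmonics >= 1,
            attack_ms >= 0, decay_ms >= 0, amplitude > 0)
  if (kind == "sweep") {
    if (is.null(f0_end_hz) || f0_end_hz <= 0) {
      stop("sweep syllables need f0_end_hz > 0")
    }
  } else {
    f0_end_hz <- NULL
  }
  if (is.null(harmonic_amps)) harmonic_amps <- 1 / seq_len(n_harmonics)
  stopifnot(length(harmonic_amps) == n_harmonics)
  structure(list(label = label, kind = kind, f0_hz = f0_hz,
                 f0_end_hz = f0_end_hz, n_harmonics = as.integer(n_harmonics),
                 harmonic_amps = harmonic_amps, duration_ms = duration_ms,
                 attack_ms = attack_ms, decay_ms = decay_ms,
                 amplitude = amplitude),
            class = "syllable_spec")
}

#' Render one syllable rendition
#'
#' Deterministic given its arguments: the waveform is a sum of harmonics of
#' a constant or linearly swept fundamental, under a trapezoidal amplitude
#' envelope, normalized to the spec's peak amplitude. Any harmonic at or
#' above the Nyquist frequency is a configuration error (aliasing).
#'
#' @param spec A [syllable_spec()].
#' @param params A [spectral_params()] (for the sample rate).
#' @param f0_override Optional rendition fundamental, Hz; for sweeps the
#'   end frequency is scaled by the same ratio.
#' @return Numeric waveform of `round(duration_ms * fs / 1000)` samples.
#' @export
synth_syllable <- function(spec, params = spectral_params(),
                           f0_override = NULL) {
  stopifnot(inherits(spec, "syllable_spec"))
  fs <- params$sample_rate_hz
  f0 <- f0_override %||% spec$f0_hz
  stopifnot(f0 > 0)
  f1 <- if (spec$kind == "sweep") f0 * spec$f0_end_hz / spec$f0_hz else f0
  if (spec$n_harmonics * max(f0, f1) >= fs / 2) {
    stop("syllable ", spec$label, ": harmonic at or above Nyquist (aliasing)")
  }
  n <- round(spec$duration_ms * fs / 1000)
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  # phase of the (possibly swept) fundamental
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur))
  w <- numeric(n)
  for (h in seq_len(spec$n_harmonics)) {
    w <- w + spec$harmonic_amps[h] * sin(h * phase)
  }
  env <- rep(1, n)
  na <- min(n, round(spec$attack_ms * fs / 1000))
  nd <- min(n, round(spec$decay_ms * fs / 1000))
  if (na > 0) env[seq_len(na)] <- seq_len(na) / na
  if (nd > 0) env[(n - nd + 1L):n] <- pmin(env[(n - nd + 1L):n],
                                           rev(seq_len(nd) / nd))
  w <- w * env
  peak <- max(abs(w))
  if (peak > 0) w <- w * spec$amplitude / peak
  w
}

#' Song grammar: syllable inventory, sequence statistics and jitter
#'
#' A song is a first-order Markov sequence of syllables separated by
#' inter-syllable gaps, over a broadband noise floor. Rendition-to-rendition
#' variability enters through the sequence (transition probabilities), gap
#' timing jitter, and per-rendition fundamental-frequency jitter -- the
#' dominant natural sources of song variability being the syllable
#' sequence itself.
#'
#' @param syllables List of [syllable_spec()] objects (the inventory).
#' @param init Label of the first syllable of every song.
#' @param transitions Named list: for each label, a named probability
#'   vector over following labels, with `"end"` terminating the song. Each
#'   row must sum to 1.
#' @param gap_ms Mean inter-syllable gap, ms.
#' @param gap_jitter_ms Gap timing jitter s.d., ms.
#' @param f0_jitter_hz Per-rendition fundamental jitter s.d., Hz.
#' @param noise_floor_db Background noise amplitude relative to the loudest
#'   syllable, dB (negative).
#' @param lead_ms,trail_ms Noise-only padding before the first and after
#'   the last syllable, ms.
#' @param max_syllables Hard cap on syllables per song.
#' @param songs_per_bout Songs generated per bout by [synth_corpus()].
#' @return An object of class `song_grammar`.
#' @export
song_grammar <- function(syllables, init, transitions,
                         gap_ms = 40, gap_jitter_ms = 2,
                         f0_jitter_hz = 30, noise_floor_db = -40,
                         lead_ms = 150, trail_ms = 80,
                         max_syllables = 25, songs_per_bout = 1) {
  labels <- vapply(syllables, `[[`, "", "label")
  stopifnot(!anyDuplicated(labels), init %in% labels,
            gap_ms > 0, gap_jitter_ms >= 0, f0_jitter_hz >= 0,
            noise_floor_db < 0, lead_ms >= 0, trail_ms >= 0,
            max_syllables >= 1, songs_per_bout >= 1)
  names(syllables) <- labels
  for (lab in names(transitions)) {
    row <- transitions[[lab]]
    if (abs(sum(row) - 1) > 1e-9) stop("transition row for '", lab,
                                       "' does not sum to 1")
    if (!all(names(row) %in% c(labels, "end"))) {
      stop("transition row for '", lab, "' references unknown labels")
    }
  }
  structure(list(syllables = syllables, init = init,
                 transitions = transitions, gap_ms = gap_ms,
                 gap_jitter_ms = gap_jitter_ms, f0_jitter_hz = f0_jitter_hz,
                 noise_floor_db = noise_floor_db, lead_ms = lead_ms,
                 trail_ms = trail_ms, max_syllables = max_syllables,
                 songs_per_bout = songs_per_bout),
            class = "song_grammar")
}

#' @export
print.song_grammar <- function(x, ...) {
  cat("<song_grammar>", length(x$syllables), "syllable types (",
      paste(names(x$syllables), collapse = " "), ") | gap",
      x$gap_ms, "+/-", x$gap_jitter_ms, "ms | f0 jitter",
      x$f0_jitter_hz, "Hz | noise", x$noise_floor_db, "dB\n")
  invisible(x)
}

#' Default five-syllable grammar
#'
#' One designated target syllable `a` -- a near-tonal harmonic stack at
#' 3.5 kHz, the kind of element whose pitch the escape-conditioning
#' experiments manipulate -- plus an introductory note `i` opening every
#' song, a descending sweep `b` that always follows the target, a low
#' harmonic stack `c`, and a rising sweep `d` that crosses the target's
#' frequency band (spectrogram-pattern matching, not instantaneous
#' frequency, is what separates them). The deterministic core `a -> b -> c`
#' makes `c` the "second syllable after the target", which the
#' half-difference interval estimator relies on.
#'
#' @return A [song_grammar()].
#' @export
default_grammar <- function() {
  syl <- list(
    syllable_spec("i", "harmonic_stack", f0_hz = 2600, n_harmonics = 2,
                  harmonic_amps = c(1, 0.5), duration_ms = 30),
    syllable_spec("a", "harmonic_stack", f0_hz = 3500, n_harmonics = 2,
                  harmonic_amps = c(1, 0.35), duration_ms = 40),
    syllable_spec("b", "sweep", f0_hz = 6000, f0_end_hz = 4000,
                  n_harmonics = 1, duration_ms = 40),
    syllable_spec("c", "harmonic_stack", f0_hz = 2200, n_harmonics = 4,
                  duration_ms = 50),
    syllable_spec("d", "sweep", f0_hz = 3000, f0_end_hz = 5000,
                  n_harmonics = 2, harmonic_amps = c(1, 0.4),
                  duration_ms = 35))
  song_grammar(
    syllables = syl, init = "i",
    transitions = list(
      i = c(a = 1),
      a = c(b = 1),
      b = c(c = 1),
      c = c(d = 0.4, a = 0.3, end = 0.3),
      d = c(a = 0.5, end = 0.5)))
}

#' Minimal single-target grammar for virtual-bird experiments
#'
#' One target rendition per song (`i -> a -> b`), short padding: keeps
#' multi-day closed-loop simulations compact while exercising the full
#' detect-pitch-feedback path on every song.
#'
#' @return A [song_grammar()].
#' @export
agent_grammar <- function() {
  g <- default_grammar()
  song_grammar(
    syllables = g$syllables, init = "i",
    transitions = list(i = c(a = 1), a = c(b = 1), b = c(end = 1)),
    lead_ms = 120, trail_ms = 60)
}

#' Remove all stochastic jitter from a grammar
#'
#' @param grammar A [song_grammar()].
#' @return The grammar with zero gap and f0 jitter (sequence randomness is
#'   untouched).
#' @export
zero_jitter <- function(grammar) {
  grammar$gap_jitter_ms <- 0
  grammar$f0_jitter_hz <- 0
  grammar
}

# draw a syllable label sequence from the grammar
draw_sequence <- function(grammar) {
  seq_labels <- character(0)
  lab <- grammar$init
  repeat {
    seq_labels <- c(seq_labels, lab)
    if (length(seq_labels) >= grammar$max_syllables) break
    row <- grammar$transitions[[lab]]
    if (is.null(row)) break
    lab <- sample(names(row), 1L, prob = row)
    if (lab == "end") break
  }
  seq_labels
}

#' Synthesize one annotated song
#'
#' Draws a syllable sequence from the grammar, renders each syllable with
#' per-rendition f0 jitter, separates them with jittered gaps, adds the
#' noise floor throughout, and returns the waveform together with
#' ground-truth annotations (label, onset, offset, rendition f0) that
#' exactly describe the emitted intervals.
#'
#' Consumes R's RNG; wrap in `withr::with_seed()` (or use the `seed`
#' argument) for reproducibility.
#'
#' @param grammar A [song_grammar()].
#' @param params A [spectral_params()].
#' @param seed Optional integer seed scoping this song's randomness.
#' @param f0_mean_override Named numeric vector overriding the mean
#'   fundamental of selected labels (the rendition jitter still applies) --
#'   the hook the virtual bird uses to sing at its current mean pitch.
#' @param noise Set `FALSE` for a clean reference recording (silent gaps).
#' @return List with `wave`, `annotations` (data frame: `label`, `onset_s`,
#'   `offset_s`, `f0_hz`), `sequence`, and `params`.
#' @export
synth_song <- function(grammar, params = spectral_params(), seed = NULL,
                       f0_mean_override = NULL, noise = TRUE) {
  gen <- function() {
    fs <- params$sample_rate_hz
    labs <- draw_sequence(grammar)
    amp_max <- max(vapply(grammar$syllables, `[[`, 0, "amplitude"))
    noise_amp <- amp_max * 10^(grammar$noise_floor_db / 20)
    pieces <- list()
    ann <- list()
    pos <- round(grammar$lead_ms * fs / 1000)   # samples before first onset
    pieces[[1]] <- numeric(pos)
    for (k in seq_along(labs)) {
      spec <- grammar$syllables[[labs[k]]]
      mu <- if (!is.null(f0_mean_override) &&
                labs[k] %in% names(f0_mean_override)) {
        f0_mean_override[[labs[k]]]
      } else spec$f0_hz
      f0 <- stats::rnorm(1, mu, grammar$f0_jitter_hz)
      f0 <- max(f0, 0.2 * mu)   # guard absurd draws
      w <- synth_syllable(spec, params, f0_override = f0)
      ann[[k]] <- data.frame(label = labs[k], onset_s = pos / fs,
                             offset_s = (pos + length(w)) / fs, f0_hz = f0,
                             stringsAsFactors = FALSE)
      pieces[[length(pieces) + 1L]] <- w
      pos <- pos + length(w)
      if (k < length(labs)) {
        gap <- stats::rnorm(1, grammar$gap_ms, grammar$gap_jitter_ms)
        gap_n <- max(round(5 * fs / 1000),
                     round(gap * fs / 1000))
        pieces[[length(pieces) + 1L]] <- numeric(gap_n)
        pos <- pos + gap_n
      }
    }
    pieces[[length(pieces) + 1L]] <- numeric(round(grammar$trail_ms * fs / 1000))
    wave <- unlist(pieces, use.names = FALSE)
    if (noise && noise_amp > 0) {
      wave <- wave + stats::runif(length(wave), -noise_amp, noise_amp)
    }
    list(wave = wave, annotations = do.call(rbind, ann), sequence = labs,
         params = params)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthesize an annotated corpus of songs
#'
#' All stochasticity flows from the single `seed`. If `dir` is given, each
#' song is written as `song_NNN.wav` with a sibling `song_NNN.csv`
#' annotation file, plus a `manifest.json` recording the seed, grammar and
#' file list so the corpus can be regenerated exactly.
#'
#' @param grammar A [song_grammar()].
#' @param n_songs Number of songs.
#' @param params A [spectral_params()].
#' @param seed Integer seed for the whole corpus.
#' @param dir Optional output directory.
#' @return List of [synth_song()] results; if `dir` was given, with a
#'   `manifest` attribute.
#' @export
synth_corpus <- function(grammar, n_songs, params = spectral_params(),
                         seed = 1, dir = NULL) {
  stopifnot(n_songs >= 1)
  songs <- withr::with_seed(seed, {
    lapply(seq_len(n_songs), function(i) synth_song(grammar, params))
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(n_songs)
    for (i in seq_len(n_songs)) {
      stem <- sprintf("song_%03d", i)
      write_wav(file.path(dir, paste0(stem, ".wav")), songs[[i]]$wave,
                params$sample_rate_hz)
      write_annotations(file.path(dir, paste0(stem, ".csv")),
                        songs[[i]]$annotations)
      files[i] <- paste0(stem, ".wav")
    }
    manifest <- list(format = "songtrigger-corpus-v1", seed = seed,
                     n_songs = n_songs,
                     sample_rate_hz = params$sample_rate_hz,
                     grammar = serialize_grammar(grammar),
                     grammar_hash = grammar_hash(grammar),
                     files = files)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(songs, "manifest") <- manifest
  }
  songs
}

# plain-list view of a grammar for manifests/hashing
serialize_grammar <- function(grammar) {
  list(
    syllables = lapply(grammar$syllables, function(s) {
      s2 <- unclass(s)
      s2[!vapply(s2, is.null, TRUE)]
    }),
    init = grammar$init,
    transitions = lapply(grammar$transitions, as.list),
    gap_ms = grammar$gap_ms, gap_jitter_ms = grammar$gap_jitter_ms,
    f0_jitter_hz = grammar$f0_jitter_hz,
    noise_floor_db = grammar$noise_floor_db,
    lead_ms = grammar$lead_ms, trail_ms = grammar$trail_ms,
    max_syllables = grammar$max_syllables,
    songs_per_bout = grammar$songs_per_bout)
}

# deterministic content hash of a grammar (md5 of its canonical JSON)
grammar_hash <- function(grammar) {
  txt <- jsonlite::toJSON(serialize_grammar(grammar), auto_unbox = TRUE,
                          digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Clean reference recording with every syllable type
#'
#' Renders the deterministic sequence `i a b c d` at zero jitter with
#' silent gaps -- the recording from which detection templates are built.
#'
#' @param grammar A [song_grammar()].
#' @param params A [spectral_params()].
#' @return A [synth_song()]-shaped list.
#' @export
reference_song <- function(grammar, params = spectral_params()) {
  g <- zero_jitter(grammar)
  g$transitions <- list(i = c(a = 1), a = c(b = 1), b = c(c = 1),
                        c = c(d = 1), d = c(end = 1))
  g$init <- "i"
  labs_all <- names(g$syllables)
  keep <- intersect(c("i", "a", "b", "c", "d"), labs_all)
  g$transitions <- g$transitions[intersect(names(g$transitions), keep)]
  synth_song(g, params, seed = 1L, noise = FALSE)
}

#' Build templates for selected labels from an annotated recording
#'
#' @param song A [synth_song()] result (or any list with `wave` and
#'   `annotations`).
#' @param labels Labels to build templates for; the first annotated
#'   rendition of each is used.
#' @param params A [spectral_params()].
#' @param duration_ms,pre_roll_ms,threshold Passed to [build_template()].
#' @return Named list of templates.
#' @export
build_templates_from_song <- function(song, labels, params = spectral_params(),
                                      duration_ms = 20, pre_roll_ms = 8,
                                      threshold = 0.8) {
  ann <- song$annotations
  out <- lapply(labels, function(lab) {
    hit <- which(ann$label == lab)
    if (!length(hit)) stop("label ", lab, " not present in the recording")
    build_template(song$wave, onset_s = ann$onset_s[hit[1]],
                   duration_ms = duration_ms, pre_roll_ms = pre_roll_ms,
                   params = params, threshold = threshold, id = lab,
                   source = "reference_song")
  })
  stats::setNames(out, labels)
}

#' Noise-floor amplitude implied by a grammar
#'
#' Convenience for gate calibration: a synthetic segment of the grammar's
#' background noise.
#'
#' @param grammar A [song_grammar()].
#' @param params A [spectral_params()].
#' @param dur_ms Segment length, ms.
#' @param seed Seed for the noise draw.
#' @return Numeric noise segment.
#' @export
noise_floor_segment <- function(grammar, params = spectral_params(),
                                dur_ms = 200, seed = 1L) {
  amp_max <- max(vapply(grammar$syllables, `[[`, 0, "amplitude"))
  a <- amp_max * 10^(grammar$noise_floor_db / 20)
  n <- round(dur_ms * params$sample_rate_hz / 1000)
  withr::with_seed(seed, stats::runif(n, -a, a))
}

#' Engine configuration matched to a grammar's noise floor
#'
#' Builds an [engine_config()] whose gate thresholds are calibrated as
#' multiples of the grammar's noise-floor rms (see [calibrate_gate()]).
#'
#' @param templates Template(s) for the bank.
#' @param grammar A [song_grammar()].
#' @param params A [spectral_params()].
#' @param ... Passed on to [engine_config()].
#' @return An [engine_config()].
#' @export
engine_config_for_grammar <- function(templates, grammar,
                                      params = spectral_params(), ...) {
  gate <- calibrate_gate(noise_floor_segment(grammar, params))
  engine_config(templates, params = params,
                gate_rms_threshold = gate$gate_rms_threshold,
                idle_return_rms_threshold = gate$idle_return_rms_threshold,
                ...)
}
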