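# Shared fixtures (built in code, cached per test run) and independent
# oracles used across the suite.

.fix <- new.env(parent = emptyenv())

fix_params <- function() {
  if (is.null(.fix$params)) .fix$params <- spectral_params()
  .fix$params
}

fix_grammar <- function() {
  if (is.null(.fix$grammar)) .fix$grammar <- default_grammar()
  .fix$grammar
}

fix_templates <- function() {
  if (is.null(.fix$templates)) {
    ref <- reference_song(fix_grammar(), fix_params())
    .fix$ref_song <- ref
    .fix$templates <- build_templates_from_song(ref, c("a", "c"),
                                                fix_params())
  }
  .fix$templates
}

fix_ref_song <- function() {
  fix_templates()
  .fix$ref_song
}

fix_config <- function() {
  if (is.null(.fix$config)) {
    .fix$config <- engine_config_for_grammar(fix_templates(), fix_grammar(),
                                             fix_params())
  }
  .fix$config
}

# the seeded 50-song corpus at generator defaults, plus cached engine logs
fix_corpus50 <- function() {
  if (is.null(.fix$corpus50)) {
    .fix$corpus50 <- synth_corpus(fix_grammar(), 50, fix_params(),
                                  seed = 101)
  }
  .fix$corpus50
}

fix_corpus50_runs <- function() {
  if (is.null(.fix$runs50)) {
    cfg <- fix_config()
    .fix$runs50 <- lapply(fix_corpus50(), function(s) {
      run_stream(s$wave, cfg)$events
    })
  }
  .fix$runs50
}

# ---- independent oracles --------------------------------------------------

# O(N^2) direct DFT magnitudes of a tapered window
naive_dft_magnitude <- function(window, params) {
  N <- params$fft_size
  stopifnot(length(window) == N)
  x <- window * params$taper_vec
  k <- 0:(N %/% 2)
  sapply(k, function(kk) {
    ang <- -2 * pi * kk * (0:(N - 1)) / N
    Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang))))
  })
}

# offline spectrogram built column by column with its own windowing logic
oracle_spectrogram <- function(wave, params) {
  hop <- params$hop
  k0 <- ceiling(params$fft_size / hop)
  times <- seq(k0 * hop, length(wave), by = hop)
  taper <- params$taper_vec
  nb <- params$n_bins
  mags <- vapply(times, function(t) {
    m <- Mod(stats::fft(wave[(t - params$fft_size + 1):t] * taper))[1:nb]
    if (params$magnitude_scale == "log") log1p(m) else m
  }, numeric(nb))
  list(times = times, mags = mags)
}

# full offline sliding-window correlation scan with per-template refractory:
# the reference the streaming engine is checked against. No amplitude gate,
# no lockout; Pearson via stats::cor.
oracle_scan <- function(wave, templates, params, refractory = NULL) {
  sg <- oracle_spectrogram(wave, params)
  ids <- sort(vapply(templates, `[[`, "", "id"))
  templates <- templates[match(ids, vapply(templates, `[[`, "", "id"))]
  if (is.null(refractory)) {
    refractory <- vapply(templates, function(tp) tp$n_cols * params$hop, 0)
  }
  refr_until <- stats::setNames(rep(0, length(ids)), ids)
  out <- list()
  for (j in seq_along(sg$times)) {
    t <- sg$times[j]
    for (i in seq_along(templates)) {
      tp <- templates[[i]]
      if (j < tp$n_cols || t < refr_until[[i]]) next
      patch <- sg$mags[, (j - tp$n_cols + 1):j]
      if (stats::sd(patch) == 0 || stats::sd(tp$patch) == 0) next
      r <- stats::cor(as.numeric(patch), as.numeric(tp$patch))
      if (r >= tp$threshold) {
        out[[length(out) + 1]] <- data.frame(time_samples = t,
                                             template_id = ids[i],
                                             correlation = r)
        refr_until[[i]] <- t + refractory[[i]]
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(time_samples = numeric(0), template_id = character(0),
               correlation = numeric(0))
}

# exhaustive optimal one-to-one matching: maximum number of detection/truth
# pairs within tolerance (checks the greedy matcher on small instances)
oracle_best_matching <- function(det, truth, tol) {
  best <- 0
  recurse <- function(d_idx, avail) {
    if (!length(d_idx)) return(0)
    d <- d_idx[1]
    rest <- d_idx[-1]
    skip <- recurse(rest, avail)
    take <- 0
    for (tr in avail) {
      if (abs(det[d] - truth[tr]) <= tol) {
        take <- max(take, 1 + recurse(rest, setdiff(avail, tr)))
      }
    }
    max(skip, take)
  }
  recurse(seq_along(det), seq_along(truth))
}

# brute-force two-sample KS D: evaluate both ECDFs at every pooled point
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(p) {
    abs(mean(x <= p) - mean(y <= p))
  }, 0))
}

# engine detections as a comparable data frame
det_table <- function(events) {
  d <- events[events$type == "detection",
              c("time_samples", "template_id", "correlation")]
  rownames(d) <- NULL
  d
}
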