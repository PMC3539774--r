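#' Spectral analysis parameters
#'
#' Bundles the short-time analysis settings shared by the streaming engine,
#' template construction and pitch estimation. Defaults follow the reference
#' apparatus: 30.3 kHz sampling, 256-point FFT (~8.4 ms) recomputed every
#' 1 ms.
#'
#' All millisecond settings are converted once to integer sample counts by
#' rounding; every downstream time is carried as an integer sample index so
#' that long streams accumulate no floating-point time drift. At 30.3 kHz a
#' 1 ms hop is 30 samples (~0.990 ms); "every 1 ms" logic counts hops.
#'
#' @param sample_rate_hz Sampling rate in Hz.
#' @param fft_size FFT length in samples; must be a power of two.
#' @param hop_ms Spectrogram column spacing in ms; converted to
#'   `round(hop_ms * sample_rate_hz / 1000)` samples (>= 1).
#' @param taper Analysis window applied before the FFT. Hann by default;
#'   `"rectangular"` disables tapering.
#' @param magnitude_scale `"linear"` (default) keeps raw FFT magnitudes, so
#'   Pearson template correlations are exactly invariant to input gain;
#'   `"log"` applies `log1p()` to each magnitude.
#' @param band_hz Optional `c(lo, hi)` frequency band (Hz) to which template
#'   correlations are restricted; `NULL` (default) uses the full band.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(sample_rate_hz = 30300,
                            fft_size = 256,
                            hop_ms = 1,
                            taper = c("hann", "rectangular"),
                            magnitude_scale = c("linear", "log"),
                            band_hz = NULL) {
  taper <- match.arg(taper)
  magnitude_scale <- match.arg(magnitude_scale)
  stopifnot(is.numeric(sample_rate_hz), length(sample_rate_hz) == 1L,
            sample_rate_hz > 0,
            is.numeric(fft_size), length(fft_size) == 1L, fft_size > 0)
  fft_size <- as.integer(fft_size)
  if (bitwAnd(fft_size, fft_size - 1L) != 0L) {
    stop("fft_size must be a power of two, got ", fft_size)
  }
  hop <- as.integer(round(hop_ms * sample_rate_hz / 1000))
  if (hop < 1L) stop("hop rounds to zero samples; increase hop_ms")
  n_bins <- fft_size %/% 2L + 1L
  freqs_hz <- (0:(n_bins - 1L)) * sample_rate_hz / fft_size
  if (!is.null(band_hz)) {
    stopifnot(is.numeric(band_hz), length(band_hz) == 2L)
    if (!(band_hz[1] >= 0 && band_hz[1] < band_hz[2] &&
          band_hz[2] <= sample_rate_hz / 2)) {
      stop("band_hz must satisfy 0 <= lo < hi <= Nyquist")
    }
  }
  taper_vec <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(fft_size - 1L)) / (fft_size - 1L))
  } else {
    rep(1, fft_size)
  }
  structure(
    list(sample_rate_hz = sample_rate_hz, fft_size = fft_size,
         hop_ms = hop_ms, hop = hop, taper = taper, taper_vec = taper_vec,
         magnitude_scale = magnitude_scale, band_hz = band_hz,
         n_bins = n_bins, freqs_hz = freqs_hz),
    class = "spectral_params")
}

#' @export
print.spectral_params <- function(x, ...) {
  cat("<spectral_params>", x$sample_rate_hz, "Hz | fft", x$fft_size,
      "| hop", x$hop, "samples |", x$taper, "taper |", x$magnitude_scale,
      "magnitudes\n")
  invisible(x)
}

# row indices used for correlation given an optional band restriction
band_rows <- function(params) {
  if (is.null(params$band_hz)) return(seq_len(params$n_bins))
  which(params$freqs_hz >= params$band_hz[1] &
          params$freqs_hz <= params$band_hz[2])
}

#' Magnitude spectrum of one analysis window
#'
#' Applies the configured taper to a window of exactly `fft_size` samples
#' and returns the magnitudes of the non-negative-frequency FFT
#' coefficients (`fft_size/2 + 1` bins). With `magnitude_scale = "log"` each
#' magnitude `m` is reported as `log(1 + m)`.
#'
#' @param window Numeric vector of length `params$fft_size`.
#' @param params A [spectral_params()] object.
#' @return Numeric vector of `params$n_bins` non-negative magnitudes.
#' @export
fft_magnitude <- function(window, params) {
  if (length(window) != params$fft_size) {
    stop("window length ", length(window), " != fft_size ", params$fft_size)
  }
  mag <- Mod(stats::fft(window * params$taper_vec))[seq_len(params$n_bins)]
  if (params$magnitude_scale == "log") mag <- log1p(mag)
  mag
}

#' Offline spectrogram of a recording
#'
#' Computes magnitude columns on the global hop grid: one column at every
#' sample index `t = k * hop` with `t >= fft_size`, each covering the
#' `fft_size` samples ending at `t`. This is exactly the grid the streaming
#' engine uses while triggered, so offline and streamed columns at the same
#' times are bit-identical.
#'
#' @param audio Numeric waveform (first sample has index 1).
#' @param params A [spectral_params()] object.
#' @return An object of class `spectrogram`: list with `magnitudes`
#'   (`n_bins x n_cols`), `times` (sample index of the newest sample of each
#'   column), `end_time`, and `params`.
#' @export
spectrogram <- function(audio, params = spectral_params()) {
  n <- length(audio)
  if (n < params$fft_size) stop("audio shorter than one FFT window")
  hop <- params$hop
  k0 <- ceiling(params$fft_size / hop)
  times <- seq(k0 * hop, n, by = hop)
  mags <- matrix(0, nrow = params$n_bins, ncol = length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    mags[, j] <- fft_magnitude(audio[(t - params$fft_size + 1L):t], params)
  }
  structure(list(magnitudes = mags, times = times,
                 end_time = times[length(times)], params = params),
            class = "spectrogram")
}

# two-pass Pearson correlation over flattened cells; internal fast path
pearson_flat <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  den <- sqrt(sum(xc * xc)) * sqrt(sum(yc * yc))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Pearson correlation between two spectrogram patches
#'
#' Flattens the two patches (optionally restricted to a frequency band) and
#' computes the Pearson correlation coefficient over all time-frequency
#' cells. This is the engine's match statistic: a detection is declared when
#' the correlation between the latest streamed patch and a template exceeds
#' the template's threshold.
#'
#' A patch with zero variance within the band is a degenerate input and
#' raises an error rather than silently returning 0; deciding whether signal
#' is present at all is the job of the rms gate, not of a correlation
#' convention.
#'
#' @param a,b Spectrogram patches: plain `n_bins x n_cols` matrices or
#'   [spectrogram()] objects. Shapes must match.
#' @param band_hz Optional `c(lo, hi)` Hz band restriction. Requires
#'   spectral parameters, taken from `a`/`b` if they are `spectrogram`
#'   objects, else from `params`.
#' @param params Optional [spectral_params()] used to resolve `band_hz` for
#'   plain matrices.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spectrogram_correlation <- function(a, b, band_hz = NULL, params = NULL) {
  if (inherits(a, "spectrogram")) { params <- params %||% a$params; a <- a$magnitudes }
  if (inherits(b, "spectrogram")) { params <- params %||% b$params; b <- b$magnitudes }
  if (!is.matrix(a) || !is.matrix(b)) stop("patches must be matrices")
  if (!all(dim(a) == dim(b))) {
    stop("patch shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  if (!is.null(band_hz)) {
    if (is.null(params)) stop("band_hz restriction requires spectral params")
    p2 <- params
    p2$band_hz <- band_hz
    rows <- band_rows(p2)
    if (length(rows) < 1L) stop("band contains no frequency bins")
    a <- a[rows, , drop = FALSE]
    b <- b[rows, , drop = FALSE]
  }
  x <- as.numeric(a); y <- as.numeric(b)
  if (length(x) < 2L) stop("patches need at least 2 cells")
  r <- pearson_flat(x, y)
  if (is.na(r)) stop("degenerate input: zero variance within the band")
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a detection template from an annotated recording
#'
#' Cuts a spectrogram patch covering `pre_roll_ms` of audio before the
#' syllable onset plus the first `duration_ms` of the syllable, on the same
#' global hop grid the engine streams on. The final column of the patch
#' corresponds (up to hop rounding) to `onset + duration`, so the detection
#' time -- the time of the last sample of the matched window -- lands inside
#' the target syllable: for a 20 ms template on a 40 ms syllable, roughly in
#' its middle.
#'
#' @param audio Numeric waveform containing the reference rendition.
#' @param onset_s Syllable onset in seconds from the start of `audio`.
#' @param duration_ms Length of the syllable part of the template, ms
#'   (default 20; longer templates such as 60 or 100 ms also work).
#' @param pre_roll_ms Length of pre-onset (inter-syllable gap) audio
#'   included, ms.
#' @param params A [spectral_params()] object.
#' @param threshold Detection threshold on the Pearson correlation,
#'   strictly inside (-1, 1); default 0.8.
#' @param id Template label.
#' @param source Free-text provenance note (e.g. recording file name).
#' @return An object of class `song_template`.
#' @export
build_template <- function(audio, onset_s, duration_ms = 20, pre_roll_ms = 8,
                           params = spectral_params(), threshold = 0.8,
                           id = "template", source = "<memory>") {
  stopifnot(is.numeric(onset_s), length(onset_s) == 1L,
            duration_ms > 0, pre_roll_ms >= 0)
  if (!(threshold > -1 && threshold < 1)) {
    stop("threshold must lie strictly between -1 and 1")
  }
  fs <- params$sample_rate_hz
  hop <- params$hop
  onset_samp <- round(onset_s * fs)
  dur_samp <- round(duration_ms * fs / 1000)
  pre_samp <- round(pre_roll_ms * fs / 1000)
  if (onset_samp - pre_samp < 0 || onset_samp + dur_samp > length(audio)) {
    stop("template interval [onset - pre_roll, onset + duration] is outside ",
         "the recording")
  }
  end_grid <- as.integer((onset_samp + dur_samp) %/% hop * hop)
  n_cols <- max(1L, as.integer((pre_samp + dur_samp) %/% hop))
  first_t <- end_grid - (n_cols - 1L) * hop
  if (first_t - params$fft_size + 1L < 1L) {
    stop("not enough audio history before the template onset for the first ",
         "FFT window")
  }
  patch <- matrix(0, nrow = params$n_bins, ncol = n_cols)
  for (j in seq_len(n_cols)) {
    t <- first_t + (j - 1L) * hop
    patch[, j] <- fft_magnitude(audio[(t - params$fft_size + 1L):t], params)
  }
  structure(
    list(id = as.character(id), patch = patch, duration_ms = duration_ms,
         pre_roll_ms = pre_roll_ms, threshold = threshold, params = params,
         n_cols = n_cols,
         # detection-time-to-onset offset actually realized after grid rounding
         post_onset_samples = as.integer(end_grid - onset_samp),
         provenance = list(source = source, onset_s = onset_s)),
    class = "song_template")
}

#' @export
print.song_template <- function(x, ...) {
  cat("<song_template>", x$id, "|", nrow(x$patch), "bins x", x$n_cols,
      "cols |", x$pre_roll_ms, "+", x$duration_ms,
      "ms | threshold", x$threshold, "\n")
  invisible(x)
}

#' Serialize a template to a JSON sidecar file
#'
#' Stores the magnitude patch (flattened column-major at full precision),
#' the spectral parameters, threshold and provenance so that a template can
#' be rebuilt bit-exactly in a later session.
#'
#' @param template A [build_template()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "song_template"))
  p <- template$params
  obj <- list(
    format = "songtrigger-template-v1",
    id = template$id,
    threshold = template$threshold,
    duration_ms = template$duration_ms,
    pre_roll_ms = template$pre_roll_ms,
    post_onset_samples = template$post_onset_samples,
    n_bins = nrow(template$patch),
    n_cols = ncol(template$patch),
    patch = as.numeric(template$patch),
    provenance = template$provenance,
    params = list(sample_rate_hz = p$sample_rate_hz, fft_size = p$fft_size,
                  hop_ms = p$hop_ms, taper = p$taper,
                  magnitude_scale = p$magnitude_scale, band_hz = p$band_hz)
  )
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a template written by [write_template()]
#'
#' @param path Path to a template JSON file.
#' @return A `song_template` object.
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "songtrigger-template-v1")) {
    stop("not a songtrigger template file: ", path)
  }
  pp <- obj$params
  params <- spectral_params(
    sample_rate_hz = pp$sample_rate_hz, fft_size = pp$fft_size,
    hop_ms = pp$hop_ms, taper = pp$taper,
    magnitude_scale = pp$magnitude_scale,
    band_hz = if (length(pp$band_hz)) as.numeric(pp$band_hz) else NULL)
  patch <- matrix(obj$patch, nrow = obj$n_bins, ncol = obj$n_cols)
  structure(
    list(id = obj$id, patch = patch, duration_ms = obj$duration_ms,
         pre_roll_ms = obj$pre_roll_ms, threshold = obj$threshold,
         params = params, n_cols = obj$n_cols,
         post_onset_samples = obj$post_onset_samples,
         provenance = as.list(obj$provenance)),
    class = "song_template")
}
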