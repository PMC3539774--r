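#' Match detections against ground-truth annotations
#'
#' Greedy chronological one-to-one matching of detection times to expected
#' detection points. Each annotated target rendition is expected to be
#' detected at `onset + expected_offset_ms` (the template's post-onset
#' extent: the detection time is the end of the matched window, which lands
#' inside the syllable). Each detection, in time order, pairs with the
#' earliest still-unmatched expected point within `tolerance_ms` -- the
#' earliest-feasible rule, which for interval-structured 1-D matching
#' always attains the maximum number of pairs; leftover truths are misses,
#' leftover detections are false positives.
#'
#' @param detections_ms Sorted detection times, ms.
#' @param truth_onsets_ms Sorted annotated target onsets, ms.
#' @param expected_offset_ms Offset from onset to expected detection time,
#'   ms (e.g. the template's syllable-part duration).
#' @param tolerance_ms Match tolerance, ms (> 0). The reference work
#'   matched detections to syllables by visual examination; a numeric rule
#'   is needed here and 10 ms -- a quarter syllable -- is the default.
#' @return An object of class `confusion_counts`: list with `n_targets`,
#'   `n_detected`, `n_missed`, `n_false_positive`, `tolerance_ms`, and the
#'   `pairs` data frame of matched (detection, truth) times.
#' @export
match_detections <- function(detections_ms, truth_onsets_ms,
                             expected_offset_ms = 0, tolerance_ms = 10) {
  stopifnot(tolerance_ms > 0)
  if (is.unsorted(detections_ms)) stop("detection times must be sorted")
  if (is.unsorted(truth_onsets_ms)) stop("truth onsets must be sorted")
  expected <- truth_onsets_ms + expected_offset_ms
  matched <- rep(FALSE, length(expected))
  pairs <- list()
  for (d in detections_ms) {
    cand <- which(!matched & abs(expected - d) <= tolerance_ms)
    if (length(cand)) {
      j <- cand[1]
      matched[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(detection_ms = d,
                                                truth_onset_ms =
                                                  truth_onsets_ms[j])
    }
  }
  n_det <- sum(matched)
  structure(
    list(n_targets = length(expected), n_detected = n_det,
         n_missed = length(expected) - n_det,
         n_false_positive = length(detections_ms) - n_det,
         tolerance_ms = tolerance_ms,
         pairs = if (length(pairs)) do.call(rbind, pairs) else
           data.frame(detection_ms = numeric(0),
                      truth_onset_ms = numeric(0))),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>", x$n_detected, "/", x$n_targets, "detected |",
      x$n_missed, "missed |", x$n_false_positive,
      "false positive(s) | tolerance", x$tolerance_ms, "ms\n")
  invisible(x)
}

#' Pair each target detection with the second-following syllable detection
#'
#' Helper for the half-difference interval estimator: for each target
#' detection time, finds the first detection of the second-following
#' syllable's template that occurs after it (and before the next target).
#' Targets without such a partner (e.g. song ended) are dropped.
#'
#' @param target_times Sorted detection times of the target syllable.
#' @param follow_times Sorted detection times of the syllable two positions
#'   after the target.
#' @return Data frame with columns `target`, `follow`.
#' @export
pair_second_following <- function(target_times, follow_times) {
  if (is.unsorted(target_times) || is.unsorted(follow_times)) {
    stop("detection times must be sorted")
  }
  out <- list()
  for (i in seq_along(target_times)) {
    t <- target_times[i]
    upper <- if (i < length(target_times)) target_times[i + 1L] else Inf
    f <- follow_times[follow_times > t & follow_times < upper]
    if (length(f)) {
      out[[length(out) + 1L]] <- data.frame(target = t, follow = f[1])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(target = numeric(0), follow = numeric(0))
}

#' Half-difference inter-syllable interval estimator
#'
#' The playback partially overlaps (and contaminates the timing of) the
#' syllable immediately following the target, so the interval between the
#' target and the next syllable is estimated as one half of the difference
#' between the detection time of the target and the detection time of the
#' *second* syllable after it. With equal spacing `d` between consecutive
#' syllables the estimator returns `d` exactly. The same computation is
#' applied to control trials for consistency.
#'
#' @param target_times Detection times of the target syllable, ms.
#' @param second_following_times Paired detection times of the second
#'   syllable after the target, ms; must exceed the paired target times.
#' @return Numeric vector of interval estimates, ms.
#' @export
half_difference_intervals <- function(target_times, second_following_times) {
  if (length(target_times) != length(second_following_times)) {
    stop("paired time vectors must have equal length")
  }
  d <- second_following_times - target_times
  if (any(d <= 0)) stop("second-following times must exceed target times")
  d / 2
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled sample points of the absolute
#' difference between the two empirical cumulative distribution functions.
#' The default p-value is the asymptotic Kolmogorov tail probability
#' evaluated at `sqrt(n m / (n + m)) * D` -- standard practice at the
#' sample sizes of song-timing experiments (hundreds of intervals). An
#' exact small-sample p (no ties) is available via the lattice-path
#' recursion.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param method `"asymptotic"` (default) or `"exact"`. Exact requires no
#'   ties across the pooled sample.
#' @return An object of class `ks_result`: list with `D`, `p`, `n_x`,
#'   `n_y`, `method`.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n <- length(x); m <- length(y)
  w <- c(x, y)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= n, 1 / n, -1 / m))
  ws <- w[ord]
  # with ties, the ECDF difference is only meaningful after the whole tie
  # group has been consumed
  last_of_group <- c(ws[-1] != ws[-length(ws)], TRUE)
  D <- max(abs(steps[last_of_group]))
  p <- if (method == "asymptotic") {
    ks_asymptotic_p(sqrt(n * m / (n + m)) * D)
  } else {
    if (anyDuplicated(w)) {
      stop("exact method requires no ties across the pooled sample")
    }
    ks_exact_p(D, n, m)
  }
  structure(list(D = D, p = p, n_x = n, n_y = m, method = method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat("<ks_result> D =", signif(x$D, 4), "| p =", signif(x$p, 4),
      "| n =", x$n_x, "vs", x$n_y, paste0("(", x$method, ")"), "\n")
  invisible(x)
}

# asymptotic Kolmogorov tail probability Q(lambda) = 2 sum (-1)^{j-1} e^{-2 j^2 lambda^2}
ks_asymptotic_p <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

# exact two-sample P(D >= d) with no ties: probability-normalized lattice DP.
# W[i, j] = P(path through (i, j) stays strictly inside the band |i/n - j/m| < d)
ks_exact_p <- function(d, n, m) {
  inside <- function(i, j) abs(i / n - j / m) < d - 1e-12
  W <- matrix(0, n + 1, m + 1)
  W[1, 1] <- 1
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      if (!inside(i, j) && !(i == n && j == m)) { W[i + 1, j + 1] <- 0; next }
      acc <- 0
      if (i > 0) acc <- acc + W[i, j + 1] * (i / (i + j))
      if (j > 0) acc <- acc + W[i + 1, j] * (j / (i + j))
      W[i + 1, j + 1] <- acc
    }
  }
  # paths must also be inside at the terminal corner for P(D < d): the corner
  # itself always has |n/n - m/m| = 0 < d, so W[n+1, m+1] = P(D < d)
  min(1, max(0, 1 - W[n + 1, m + 1]))
}

#' Per-day pitch summaries
#'
#' Aggregates rendition pitches by day: mean, standard error of the mean,
#' and rendition count, days in ascending order. A day with a single
#' rendition reports s.e.m. 0 and is flagged (`singleton`); empty days are
#' simply absent.
#'
#' @param day Integer day index per rendition.
#' @param pitch_hz Pitch per rendition, Hz.
#' @return Data frame with `day`, `mean_hz`, `sem_hz`, `n`, `singleton`.
#' @export
daily_pitch_summary <- function(day, pitch_hz) {
  stopifnot(length(day) == length(pitch_hz))
  keep <- !is.na(pitch_hz) & !is.na(day)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " renditions with missing day or pitch")
  }
  day <- day[keep]; pitch_hz <- pitch_hz[keep]
  if (!length(day)) {
    return(data.frame(day = integer(0), mean_hz = numeric(0),
                      sem_hz = numeric(0), n = integer(0),
                      singleton = logical(0)))
  }
  days <- sort(unique(day))
  out <- lapply(days, function(d) {
    p <- pitch_hz[day == d]
    n <- length(p)
    data.frame(day = d, mean_hz = mean(p),
               sem_hz = if (n > 1) stats::sd(p) / sqrt(n) else 0,
               n = n, singleton = n == 1L)
  })
  do.call(rbind, out)
}
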