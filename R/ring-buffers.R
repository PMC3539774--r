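#' Fixed-capacity circular buffer over raw audio samples
#'
#' A `sample_ring` holds the most recent `capacity` samples of a stream and
#' gives constant-time access to any suffix of them without disturbing
#' acquisition order. It is the in-memory core of the streaming engine: the
#' acquisition loop pushes samples one-by-one (or in chunks) and the
#' detector reads windows ending at the current sample.
#'
#' Rings are environments, i.e. they have reference semantics: `ring_push()`
#' mutates its argument in place and returns it invisibly. Reads
#' ([latest_window()]) never mutate state. Internally the storage lives in
#' the ring's own closure environment so pushes are true in-place writes,
#' cheap enough to run at audio rate.
#'
#' @param capacity Maximum number of samples retained (>= 1). Once full,
#'   each new sample overwrites the single oldest one.
#' @return An object of class `sample_ring`.
#' @seealso [spectro_ring()] for the FFT-column analogue.
#' @export
#' @examples
#' r <- sample_ring(3)
#' ring_push(r, c(1, 2, 3, 4, 5))
#' latest_window(r, 3)  # 3 4 5
sample_ring <- function(capacity) {
  stopifnot(is.numeric(capacity), length(capacity) == 1L, is.finite(capacity),
            capacity >= 1)
  capacity <- as.integer(capacity)
  buf <- numeric(capacity)
  n_pushed <- 0
  push <- function(x) {
    n <- length(x)
    if (n == 0L) return(invisible(NULL))
    if (n >= capacity) {
      keep <- x[(n - capacity + 1L):n]
      g <- n_pushed + (n - capacity + 1):n
      buf[(g - 1) %% capacity + 1] <<- keep
    } else {
      idx <- (n_pushed + seq_len(n) - 1) %% capacity + 1
      buf[idx] <<- x
    }
    n_pushed <<- n_pushed + n
    invisible(NULL)
  }
  window <- function(n) {
    idx <- (n_pushed - n + seq_len(n) - 1) %% capacity + 1
    buf[idx]
  }
  reset <- function() {
    n_pushed <<- 0
    invisible(NULL)
  }
  ring <- environment()
  class(ring) <- c("sample_ring", "ring")
  ring
}

#' Fixed-capacity circular buffer over spectrogram columns
#'
#' A `spectro_ring` stores FFT magnitude columns (all with the same bin
#' count) in arrival order, together with the sample index of the newest
#' sample contributing to each column. The streaming engine fills it at the
#' hop rate while triggered, and reads the most recent `k` columns to form
#' the patch correlated against a template.
#'
#' @param n_bins Number of frequency bins per column.
#' @param capacity Maximum number of columns retained.
#' @return An object of class `spectro_ring`.
#' @export
spectro_ring <- function(n_bins, capacity) {
  stopifnot(is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 1,
            is.numeric(capacity), length(capacity) == 1L, capacity >= 1)
  n_bins <- as.integer(n_bins)
  capacity <- as.integer(capacity)
  buf <- matrix(0, nrow = n_bins, ncol = capacity)
  times <- numeric(capacity)
  n_pushed <- 0
  push <- function(x, time) {
    idx <- n_pushed %% capacity + 1
    buf[, idx] <<- x
    times[idx] <<- time
    n_pushed <<- n_pushed + 1
    invisible(NULL)
  }
  cols <- function(k) {
    idx <- (n_pushed - k + seq_len(k) - 1) %% capacity + 1
    buf[, idx, drop = FALSE]
  }
  col_times <- function(k) {
    idx <- (n_pushed - k + seq_len(k) - 1) %% capacity + 1
    times[idx]
  }
  reset <- function() {
    n_pushed <<- 0
    invisible(NULL)
  }
  ring <- environment()
  class(ring) <- c("spectro_ring", "ring")
  ring
}

#' Push items into a ring buffer
#'
#' Appends new elements in arrival order. If the ring is full the oldest
#' elements are discarded, one per new element. The total-pushed counter
#' advances by the number of items pushed and never decreases.
#'
#' @param ring A [sample_ring()] or [spectro_ring()].
#' @param x For a sample ring, a numeric vector of samples (possibly length
#'   one). For a spectro ring, a single magnitude column whose length must
#'   equal the ring's `n_bins`.
#' @param time For a spectro ring, the sample index of the newest sample
#'   contributing to the pushed column.
#' @return The ring, invisibly (mutated in place).
#' @export
ring_push <- function(ring, x, time = NA_real_) UseMethod("ring_push")

#' @export
ring_push.sample_ring <- function(ring, x, time = NA_real_) {
  ring$push(as.numeric(x))
  invisible(ring)
}

#' @export
ring_push.spectro_ring <- function(ring, x, time = NA_real_) {
  x <- as.numeric(x)
  if (length(x) != ring$n_bins) {
    stop("bin-count mismatch: column has ", length(x), " bins, ring expects ",
         ring$n_bins)
  }
  ring$push(x, time)
  invisible(ring)
}

#' Total number of items ever pushed into a ring
#'
#' @param ring A ring buffer.
#' @return Monotone counter; for a sample ring this is the sample index of
#'   the newest element.
#' @export
total_pushed <- function(ring) ring$n_pushed

#' Read the most recent samples from a sample ring
#'
#' Returns exactly the last `n` pushed samples, oldest first, bit-identical
#' to the values pushed. The ring is not modified.
#'
#' @param ring A [sample_ring()].
#' @param n Window length; must satisfy
#'   `1 <= n <= min(capacity, total_pushed(ring))`.
#' @return Numeric vector of length `n`.
#' @export
latest_window <- function(ring, n) {
  if (!inherits(ring, "sample_ring")) stop("latest_window() needs a sample_ring")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n > min(ring$capacity, ring$n_pushed)) {
    stop("window length out of range: n = ", n, ", available = ",
         min(ring$capacity, ring$n_pushed))
  }
  ring$window(as.integer(n))
}

#' Read the most recent columns from a spectro ring
#'
#' Returns the last `k` pushed magnitude columns in chronological order as
#' an `n_bins x k` matrix. The ring is not modified.
#'
#' @param ring A [spectro_ring()].
#' @param k Number of columns; `1 <= k <=` stored column count.
#' @return Numeric matrix, `n_bins` rows by `k` columns.
#' @export
latest_spectrogram <- function(ring, k) {
  if (!inherits(ring, "spectro_ring")) {
    stop("latest_spectrogram() needs a spectro_ring")
  }
  stored <- min(ring$capacity, ring$n_pushed)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > stored) {
    stop("column count out of range: k = ", k, ", stored = ", stored)
  }
  ring$cols(as.integer(k))
}

#' Sample-index timestamps of the most recent columns
#'
#' @param ring A [spectro_ring()].
#' @param k Number of columns, as in [latest_spectrogram()].
#' @return Numeric vector of the sample indices of the newest contributing
#'   sample of each returned column, chronological order.
#' @export
latest_column_times <- function(ring, k) {
  stored <- min(ring$capacity, ring$n_pushed)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > stored) {
    stop("column count out of range")
  }
  ring$col_times(as.integer(k))
}

#' Reset a ring to its empty state
#'
#' Used by the engine when entering triggered mode so that spectrogram
#' patches never span an idle period.
#'
#' @param ring A ring buffer.
#' @return The ring, invisibly.
#' @export
ring_reset <- function(ring) {
  ring$reset()
  invisible(ring)
}

#' @export
print.sample_ring <- function(x, ...) {
  cat("<sample_ring> capacity", x$capacity, "| pushed", x$n_pushed, "\n")
  invisible(x)
}

#' @export
print.spectro_ring <- function(x, ...) {
  cat("<spectro_ring>", x$n_bins, "bins | capacity", x$capacity,
      "| pushed", x$n_pushed, "\n")
  invisible(x)
}
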