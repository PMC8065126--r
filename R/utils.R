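#' Derive a child seed from a parent seed and index path
#'
#' A counter-based scheme: the parent seed is mixed with each index through a
#' multiplicative-congruential hash, so any subset of a synthetic study
#' (one subject, one trial, one channel) regenerates identically without
#' simulating everything before it. Results stay below 2^31 so they are valid
#' arguments to [set.seed()].
#'
#' @param seed parent integer seed
#' @param ... integer indices (subject, load, trial, channel, ...)
#' @return an integer seed
#' @export
#' @examples
#' child_seed(1, 3, 2) # deterministic, != child_seed(1, 2, 3)
child_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(seed)) %% m)
  for (x in c(...)) {
    # 69069 * h < 2^48: exact in double arithmetic
    h <- (h * 69069 + abs(as.numeric(x)) + 1) %% m
  }
  as.integer(h %% 2147483646L + 1L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop("`", name, "` must be finite", call. = FALSE)
  }
  invisible(x)
}

hann_window <- function(n) {
  if (n == 1) {
    return(1)
  }
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# analytic signal via FFT (Hilbert transform companion)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# zero-phase FFT band-pass with cosine-tapered edges; used by the synthesis
# routines (the analysis filter bank uses FIR filters, see pac functions)
fft_bandpass <- function(x, fs, lo, hi, taper_frac = 0.1) {
  n <- length(x)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)
  gain <- as.numeric(f >= lo & f <= hi)
  bw <- hi - lo
  tw <- taper_frac * bw
  if (tw > 0) {
    up <- f >= lo - tw & f < lo
    gain[up] <- 0.5 + 0.5 * cos(pi * (lo - f[up]) / tw)
    dn <- f > hi & f <= hi + tw
    gain[dn] <- 0.5 + 0.5 * cos(pi * (f[dn] - hi) / tw)
  }
  Re(fft(fft(x) * gain, inverse = TRUE) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
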