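#' Generate scale-free (1/f) background noise
#'
#' Spectral synthesis: complex spectrum with random phases and amplitude
#' proportional to \eqn{f^{-\chi/2}}, inverse-transformed to a real series,
#' so expected power decays as \eqn{f^{-\chi}}. The series is returned
#' zero-mean with unit variance. `chi = 0` is white noise; larger exponents
#' give steeper, "more excitable-looking" spectra. The exponent is the
#' quantity the aperiodic-slope estimator ([fit_slope()]) is meant to
#' recover (with opposite sign, as a log-log slope).
#'
#' @param chi aperiodic exponent (>= 0)
#' @param duration seconds
#' @param fs sampling rate, Hz
#' @param seed integer seed
#' @return numeric vector of `duration * fs` samples
#' @export
#' @examples
#' x <- gen_aperiodic(1, duration = 2, fs = 250, seed = 1)
#' c(mean(x), var(x)) # ~0, 1
gen_aperiodic <- function(chi, duration, fs, seed = 1) {
  if (!is.finite(chi) || chi < 0) {
    stop("`chi` must be a finite non-negative exponent", call. = FALSE)
  }
  n <- round(duration * fs)
  stopifnot(n >= 2)
  with_seed(seed, {
    freqs <- seq(0, fs / 2, by = fs / n)
    n_pos <- length(freqs) - 1 # positive-frequency bins excluding DC
    amp <- freqs[-1]^(-chi / 2)
    phase <- runif(n_pos, 0, 2 * pi)
    half <- amp * exp(1i * phase)
    spec <- complex(n)
    spec[2:(n_pos + 1)] <- half
    # hermitian symmetry for a real series
    if (n %% 2 == 0) {
      spec[n_pos + 1] <- Re(spec[n_pos + 1]) # Nyquist bin must be real
      spec[seq(n, n_pos + 2)] <- Conj(spec[2:n_pos])
    } else {
      spec[seq(n, n_pos + 2)] <- Conj(spec[2:(n_pos + 1)])
    }
    x <- Re(fft(spec, inverse = TRUE)) / n
    x <- x - mean(x)
    x / sd(x)
  })
}

#' Generate tapered oscillatory bursts with known episode intervals
#'
#' Sinusoidal bursts with Hann-tapered edges are placed at random
#' non-overlapping positions so that they occupy approximately `abundance`
#' of the window. Each burst lasts at least three cycles (the duration
#' criterion episode detection applies). The true intervals are returned so
#' detection can be scored against ground truth.
#'
#' @param freq burst frequency, Hz
#' @param abundance target fraction of the window occupied by bursts, in
#'   `[0, 1]`
#' @param snr burst power relative to a unit-variance background
#' @param duration seconds
#' @param fs Hz
#' @param seed integer seed
#' @param cycles_range burst durations are drawn uniformly from this range
#'   of cycles (minimum 3)
#' @return list with `signal` (numeric vector) and `intervals`
#'   (tibble with `onset`, `offset` in seconds)
#' @export
gen_bursts <- function(freq, abundance, snr, duration, fs, seed = 1,
                       cycles_range = c(3, 6)) {
  stopifnot(freq > 0, snr >= 0, duration > 0, fs > 2 * freq)
  if (abundance < 0 || abundance > 1) {
    stop("`abundance` must lie in [0, 1]", call. = FALSE)
  }
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  empty <- tibble::tibble(onset = numeric(), offset = numeric())
  if (abundance == 0) {
    return(list(signal = numeric(n), intervals = empty))
  }
  min_burst <- 3 / freq
  if (abundance * duration < min_burst - 1e-9) {
    stop("`abundance` demands bursts shorter than 3 cycles", call. = FALSE)
  }
  amp <- sqrt(2 * snr) # sinusoid power amp^2/2 = snr x unit background power
  if (abundance >= 1 - min_burst / duration / 2) {
    # one continuous oscillation spanning the window
    sig <- amp * sin(2 * pi * freq * tt)
    return(list(
      signal = sig,
      intervals = tibble::tibble(onset = 0, offset = duration)
    ))
  }
  with_seed(seed, {
    target <- abundance * duration
    lens <- numeric(0)
    while (sum(lens) < target - min_burst / 2) {
      cyc <- runif(1, max(3, cycles_range[1]), max(3, cycles_range[2]))
      lens <- c(lens, cyc / freq)
    }
    # trim the last burst so total time matches the target (>= 3 cycles)
    overshoot <- sum(lens) - target
    if (overshoot > 0) {
      k <- length(lens)
      lens[k] <- max(min_burst, lens[k] - overshoot)
    }
    # place bursts by distributing the free time into random gaps
    free <- duration - sum(lens)
    gaps <- runif(length(lens) + 1)
    gaps <- gaps / sum(gaps) * free
    onsets <- cumsum(gaps)[seq_along(lens)] + cumsum(c(0, lens[-length(lens)]))
    sig <- numeric(n)
    for (k in seq_along(lens)) {
      i0 <- max(1L, round(onsets[k] * fs) + 1L)
      i1 <- min(n, i0 + round(lens[k] * fs) - 1L)
      idx <- i0:i1
      taper_n <- max(2L, round(fs / freq)) # one-cycle Hann ramps
      env <- rep(1, length(idx))
      ramp <- 0.5 - 0.5 * cos(pi * seq_len(taper_n) / (taper_n + 1))
      m <- min(taper_n, floor(length(idx) / 2))
      env[seq_len(m)] <- ramp[seq_len(m)]
      env[length(idx) + 1 - seq_len(m)] <- ramp[seq_len(m)]
      sig[idx] <- sig[idx] + amp * env * sin(2 * pi * freq * (tt[idx] - tt[idx[1]]))
    }
    list(
      signal = sig,
      intervals = tibble::tibble(
        onset = onsets,
        offset = onsets + lens
      )
    )
  })
}

#' Generate phase-amplitude coupled high-frequency activity
#'
#' Band-limited Gaussian noise in `amp_band` whose instantaneous amplitude is
#' modulated by the phase of a low-frequency carrier:
#' envelope = (1 + kappa * cos(phase - preferred_phase)) / 2. With
#' `kappa = 0` the envelope is phase-independent; with `kappa = 1` the
#' envelope vanishes at the anti-preferred phase. The result is the kind of
#' coupling a phase-binned modulation index ([pac_mi()]) detects.
#'
#' @param carrier_freq Hz of the slow carrier whose phase modulates amplitude
#' @param amp_band length-2 Hz range of the fast, amplitude-modulated band
#' @param kappa coupling depth in `[0, 1]`
#' @param duration seconds
#' @param fs Hz
#' @param seed integer seed
#' @param preferred_phase radians at which the envelope is maximal
#' @param phase optional externally supplied carrier phase series (radians);
#'   default is the phase of a pure `carrier_freq` sinusoid
#' @return numeric vector; attribute `"phase"` holds the carrier phase used
#' @export
gen_pac <- function(carrier_freq, amp_band, kappa, duration, fs, seed = 1,
                    preferred_phase = 0, phase = NULL) {
  if (kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]", call. = FALSE)
  if (amp_band[1] <= carrier_freq || amp_band[2] >= fs / 2) {
    stop("`amp_band` must lie inside (carrier_freq, fs/2)", call. = FALSE)
  }
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  if (is.null(phase)) phase <- 2 * pi * carrier_freq * tt
  stopifnot(length(phase) == n)
  carrier_noise <- with_seed(seed, rnorm(n))
  g <- fft_bandpass(carrier_noise, fs, amp_band[1], amp_band[2])
  g <- g / sd(g)
  env <- (1 + kappa * cos(phase - preferred_phase)) / 2
  out <- g * env
  attr(out, "phase") <- phase
  out
}

#' Generate a single-trial pupil trace with a load-scaled phasic response
#'
#' A stimulus-locked dilation transient (gamma-shaped kernel peaking about
#' one second after onset) scaled by `gain`, on top of slow drifting noise.
#' The phasic-arousal metric downstream is the median first derivative in
#' the early stimulus window, so `gain` is the planted quantity
#' [extract_phasic()] should order correctly across loads.
#'
#' @param gain amplitude of the dilation transient (arbitrary diameter units)
#' @param duration seconds
#' @param fs Hz
#' @param seed integer seed
#' @param t0 epoch start relative to stimulus onset, seconds
#' @param noise_sd SD of the additive slow noise
#' @return numeric vector
#' @export
gen_pupil_trace <- function(gain, duration, fs, seed = 1, t0 = -1,
                            noise_sd = 0.05) {
  n <- round(duration * fs)
  tt <- t0 + (seq_len(n) - 1) / fs
  shape <- 4
  scale <- 0.25 # peak at shape*scale = 1 s post-onset
  kern <- ifelse(tt > 0, (tt / scale)^shape * exp(shape - tt / scale) / shape^shape, 0)
  noise <- with_seed(seed, {
    raw <- cumsum(rnorm(n)) / sqrt(n) # slow random-walk drift
    raw - mean(raw)
  })
  5 + gain * kern + noise_sd * noise
}
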