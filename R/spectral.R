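new_tfr <- function(power, freqs, times, method, log10 = TRUE,
                    channels = NULL, flags = character()) {
  structure(
    list(
      power = power, # trial x channel x freq x time
      freqs = freqs, times = times, method = method, log10 = log10,
      channels = channels %||% sprintf("ch%02d", dim(power)[2]),
      flags = flags
    ),
    class = "tfr"
  )
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr:%s> %d trials x %d channels x %d freqs [%.2g-%.2g Hz] x %d times%s\n",
    x$method, d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4],
    if (x$log10) " (log10)" else ""
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

log10_floor <- function(p) {
  # floor linear power at eps * max before log10, so silent channels do not
  # produce -Inf; recorded as a flag by callers
  mx <- max(p, na.rm = TRUE)
  floor_val <- if (mx > 0) .Machine$double.eps * mx else .Machine$double.xmin
  log10(pmax(p, floor_val))
}

#' Morlet wavelet time-frequency transform
#'
#' Complex Morlet wavelets with `cycles` cycles per frequency
#' (\eqn{\sigma_t = cycles / (2\pi f)}), applied by FFT convolution. Power is
#' log10-transformed per single trial with no baseline. Time points where the
#' wavelet support (3 sigma) extends beyond the epoch are marked `NA` rather
#' than zero-padded.
#'
#' @param trials a [trial_set()]
#' @param freqs center frequencies, Hz
#' @param cycles wavelet cycles (default 7)
#' @param step output time step, seconds (default 0.05)
#' @param log10 log10-transform single-trial power (default TRUE)
#' @return a `tfr` object
#' @export
morlet_tfr <- function(trials, freqs, cycles = 7, step = 0.05, log10 = TRUE) {
  fs <- trials$fs
  if (max(freqs) >= fs / 2) stop("max frequency must be below Nyquist", call. = FALSE)
  nt <- length(trials$times)
  epoch_len <- nt / fs
  support <- 6 * cycles / (2 * pi * min(freqs)) # +/- 3 sigma_t
  if (support >= epoch_len) {
    stop(sprintf(
      "epoch too short for a %d-cycle wavelet at %.3g Hz", cycles, min(freqs)
    ), call. = FALSE)
  }
  dec <- max(1L, round(step * fs))
  keep <- seq(1L, nt, by = dec)
  out_times <- trials$times[keep]
  d <- dim(trials$data)
  pow <- array(NA_real_, c(d[1], d[2], length(freqs), length(keep)))
  nfft <- nt
  tvec <- (seq_len(nt) - 1) / fs
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma_t <- cycles / (2 * pi * f)
    # wavelet built on the epoch grid, centered at t = 0 via wrap-around
    tc <- ifelse(tvec <= nt / fs / 2, tvec, tvec - nt / fs)
    w <- exp(-tc^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * f * tc)
    w <- w / sqrt(sum(Mod(w)^2)) # unit energy
    W <- fft(w)
    half_sup <- 3 * sigma_t
    valid <- out_times >= trials$times[1] + half_sup &
      out_times <= trials$times[nt] - half_sup
    for (tr in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        conv <- fft(fft(trials$data[tr, ch, ]) * W, inverse = TRUE) / nfft
        p <- Mod(conv[keep])^2
        p[!valid] <- NA_real_
        pow[tr, ch, fi, ] <- p
      }
    }
  }
  if (log10) {
    for (tr in seq_len(d[1])) pow[tr, , , ] <- log10_floor(pow[tr, , , ])
  }
  out <- new_tfr(pow, freqs, out_times, "wavelet", log10, trials$channels,
    flags = c("power-floored"))
  out$cycles <- cycles
  out
}

dpss_tapers <- function(n, nw, k) {
  # Slepian sequences via the classic symmetric tridiagonal eigenproblem
  w <- nw / n
  i <- seq_len(n)
  diag_v <- ((n - 1 - 2 * (i - 1))^2 / 4) * cos(2 * pi * w)
  off_v <- (i[-n] * (n - i[-n])) / 2
  m <- matrix(0, n, n)
  m[cbind(i, i)] <- diag_v
  m[cbind(i[-n], i[-n] + 1)] <- off_v
  m[cbind(i[-n] + 1, i[-n])] <- off_v
  e <- eigen(m, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign convention (positive mean for even-order tapers)
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (j %% 2 == 1 && sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  }
  tapers
}

#' Multitaper estimate of high-frequency (gamma) power
#'
#' Sliding-window multitaper spectrogram with five discrete prolate
#' spheroidal (Slepian) tapers, 400 ms windows, 200 ms steps and 8 Hz
#' spectral smoothing, covering 45-90 Hz in 2.5 Hz steps. Single-trial power
#' is log10-transformed; normalization is a separate step
#' ([gamma_normalize()]).
#'
#' @param trials a [trial_set()]
#' @param window_s window length, seconds
#' @param step_s step size, seconds
#' @param band frequency range, Hz
#' @param smoothing half-bandwidth of spectral smoothing, Hz
#' @param n_tapers number of Slepian tapers
#' @return a `tfr` object
#' @export
multitaper_gamma <- function(trials, window_s = 0.4, step_s = 0.2,
                             band = c(45, 90), smoothing = 8, n_tapers = 5) {
  fs <- trials$fs
  if (fs < 2 * band[2]) stop("sampling rate too low for the requested band", call. = FALSE)
  n_win <- round(window_s * fs)
  nw <- window_s * smoothing # time-(half)bandwidth product
  k_max <- max(1L, floor(2 * nw - 1))
  if (n_tapers > k_max) {
    stop(sprintf(
      "%d tapers requested but bandwidth supports at most %d", n_tapers, k_max
    ), call. = FALSE)
  }
  tapers <- dpss_tapers(n_win, nw, n_tapers)
  df <- 1 / window_s
  freqs <- seq(ceiling(band[1] / df) * df, band[2], by = df)
  bin <- round(freqs * window_s) + 1L
  d <- dim(trials$data)
  nt <- length(trials$times)
  starts <- seq(1L, nt - n_win + 1L, by = max(1L, round(step_s * fs)))
  out_times <- trials$times[starts] + window_s / 2
  pow <- array(NA_real_, c(d[1], d[2], length(freqs), length(starts)))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- trials$data[tr, ch, ]
      for (wi in seq_along(starts)) {
        seg <- x[starts[wi]:(starts[wi] + n_win - 1L)]
        seg <- seg - mean(seg)
        p <- 0
        for (j in seq_len(n_tapers)) {
          sp <- fft(seg * tapers[, j])
          p <- p + Mod(sp[bin])^2
        }
        pow[tr, ch, , wi] <- p / n_tapers / fs
      }
    }
  }
  for (tr in seq_len(d[1])) pow[tr, , , ] <- log10_floor(pow[tr, , , ])
  new_tfr(pow, freqs, out_times, "multitaper", TRUE, trials$channels,
    flags = "power-floored")
}

#' Single-trial z-normalization of gamma power against a pre-stimulus baseline
#'
#' Per frequency and channel: subtract each trial's mean baseline power,
#' divide by the across-trial standard deviation of baseline power, then
#' subtract the condition-mean normalized baseline so the baseline window
#' averages to zero by construction. Operates on (and expects) log10 power.
#'
#' @param tfr a `tfr` from [multitaper_gamma()] (one condition's trials)
#' @param baseline length-2 window in seconds relative to stimulus onset
#' @return a `tfr` flagged `"z-normalized"`
#' @export
gamma_normalize <- function(tfr, baseline = c(-0.7, -0.1)) {
  if ("z-normalized" %in% tfr$flags) {
    stop("tfr is already z-normalized; refusing to normalize twice", call. = FALSE)
  }
  bidx <- time_index(tfr$times, baseline)
  if (!length(bidx)) stop("baseline window outside epoch", call. = FALSE)
  d <- dim(tfr$power)
  if (d[1] < 2) stop("need >= 2 trials for the across-trial baseline SD", call. = FALSE)
  out <- tfr$power
  for (ch in seq_len(d[2])) {
    for (fi in seq_len(d[3])) {
      b <- tfr$power[, ch, fi, bidx, drop = FALSE]
      btrial <- apply(b, 1, mean, na.rm = TRUE)
      sdb <- sd(btrial)
      if (!is.finite(sdb) || sdb == 0) sdb <- 1
      z <- sweep(tfr$power[, ch, fi, , drop = FALSE], 1, btrial, "-") / sdb
      # remove the condition-mean baseline shift
      cond_base <- mean(z[, 1, 1, bidx], na.rm = TRUE)
      out[, ch, fi, ] <- z - cond_base
    }
  }
  tfr$power <- out
  tfr$flags <- c(tfr$flags, "z-normalized")
  tfr
}

#' Trial-averaged spectral power on a log-spaced grid
#'
#' Hann-tapered FFT over an analysis window (default the final 2.5 s of
#' stimulus presentation), zero-padded (default to 10 s) so that
#' log-spaced target frequencies fall on the padded grid; trial-averaged and
#' log10-transformed. The default grid is 41 log-spaced frequencies in
#' 2-64 Hz, the substrate for aperiodic-slope fitting.
#'
#' @param trials a [trial_set()]
#' @param span analysis window, seconds (relative to stimulus onset)
#' @param freqs target frequencies, Hz
#' @param pad_s zero-pad length in seconds (`NULL` = no padding)
#' @param window `"hann"` or `"rect"`
#' @param log10 log10-transform the trial-averaged power
#' @return object of class `psd`: list with `power` (channel x frequency),
#'   `freqs`, metadata
#' @export
welch_psd <- function(trials, span = c(0.5, 3), freqs = log_freqs(2, 64, 41),
                      pad_s = 10, window = c("hann", "rect"), log10 = TRUE) {
  window <- match.arg(window)
  fs <- trials$fs
  idx <- time_index(trials$times, span)
  if (!length(idx)) stop("analysis window outside epoch", call. = FALSE)
  if (max(freqs) > fs / 2) stop("requested frequency above Nyquist", call. = FALSE)
  n <- length(idx)
  nfft <- if (is.null(pad_s)) n else max(n, round(pad_s * fs))
  df <- fs / nfft
  bin <- round(freqs / df) + 1L
  grid_freqs <- (bin - 1) * df
  w <- if (window == "hann") hann_window(n) else rep(1, n)
  u <- sum(w^2) * fs # window energy x fs: power spectral density scaling
  d <- dim(trials$data)
  pow <- matrix(0, d[2], length(freqs))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- trials$data[tr, ch, idx]
      x <- (x - mean(x)) * w
      sp <- fft(c(x, numeric(nfft - n)))
      pow[ch, ] <- pow[ch, ] + Mod(sp[bin])^2 / u
    }
  }
  pow <- pow / d[1]
  structure(
    list(
      power = if (log10) log10_floor(pow) else pow,
      freqs = grid_freqs, df = df, log10 = log10, window = window,
      n_samples = n, pad_s = pad_s, channels = trials$channels,
      flags = if (log10) "log10" else character()
    ),
    class = "psd"
  )
}

#' Log-spaced frequency grid
#' @param lo,hi range in Hz
#' @param n number of frequencies
#' @return numeric vector
#' @export
log_freqs <- function(lo = 2, hi = 64, n = 41) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Fit the aperiodic (1/f) spectral slope
#'
#' Ordinary least-squares regression of log10 power on log10 frequency,
#' excluding the narrowband alpha range (default 7-13 Hz) so an oscillatory
#' peak does not bias the aperiodic estimate. The slope is the negative of
#' the generating aperiodic exponent; flatter (less negative) slopes are
#' read as a higher excitation/inhibition ratio.
#'
#' @param psd a `psd` object from [welch_psd()]
#' @param fit_range Hz range used for the fit
#' @param exclude list of Hz ranges to drop from the fit
#' @return tibble with one row per channel: `channel`, `slope`, `intercept`,
#'   `r_squared`, `n_freqs`
#' @export
fit_slope <- function(psd, fit_range = c(2, 64), exclude = list(c(7, 13))) {
  keep <- psd$freqs >= fit_range[1] & psd$freqs <= fit_range[2]
  for (ex in exclude) keep <- keep & !(psd$freqs >= ex[1] & psd$freqs <= ex[2])
  if (sum(keep) < 10) stop("fewer than 10 frequencies retained for the slope fit", call. = FALSE)
  lf <- log10(psd$freqs[keep])
  lp <- if (psd$log10) psd$power[, keep, drop = FALSE] else log10(psd$power[, keep, drop = FALSE])
  out <- purrr::map_dfr(seq_len(nrow(lp)), function(ch) {
    fit <- lm(lp[ch, ] ~ lf)
    sst <- sum((lp[ch, ] - mean(lp[ch, ]))^2)
    tibble::tibble(
      channel = psd$channels[ch],
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = if (sst > 0) 1 - sum(residuals(fit)^2) / sst else NA_real_,
      n_freqs = sum(keep)
    )
  })
  attr(out, "exclude") <- exclude
  out
}

#' Steady-state visual-evoked potential estimate with neighbor normalization
#'
#' Power at the stimulation frequency (default 30 Hz) from sliding 1 s
#' Hann-tapered windows (100 ms steps), averaged over trials within the
#' condition, then normalized by subtracting the mean of the two neighboring
#' frequencies (default 28 and 32 Hz, removing broadband/aperiodic effects)
#' and finally by subtracting a pre-stimulus temporal baseline.
#'
#' @param trials a [trial_set()] holding one condition
#' @param f0 stimulation frequency, Hz
#' @param neighbors length-2 neighbor frequencies, Hz
#' @param baseline temporal baseline window, seconds
#' @param window_s,step_s sliding-window parameters
#' @return tibble: `channel`, `time`, `ssvep` (linear power units)
#' @export
ssvep_estimate <- function(trials, f0 = 30, neighbors = c(28, 32),
                           baseline = c(-0.7, -0.1),
                           window_s = 1, step_s = 0.1) {
  fs <- trials$fs
  n_win <- round(window_s * fs)
  df <- 1 / window_s
  targets <- c(f0, neighbors)
  if (any(abs(targets * window_s - round(targets * window_s)) > 1e-6)) {
    stop("f0/neighbor frequencies must lie on the window frequency grid", call. = FALSE)
  }
  bins <- round(targets * window_s) + 1L
  nt <- length(trials$times)
  starts <- seq(1L, nt - n_win + 1L, by = max(1L, round(step_s * fs)))
  times <- trials$times[starts] + window_s / 2
  d <- dim(trials$data)
  w <- hann_window(n_win)
  u <- sum(w^2)
  # trial-averaged power per channel x window x target frequency
  pow <- array(0, c(d[2], length(starts), 3))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- trials$data[tr, ch, ]
      for (wi in seq_along(starts)) {
        seg <- x[starts[wi]:(starts[wi] + n_win - 1L)]
        sp <- fft((seg - mean(seg)) * w)
        pow[ch, wi, ] <- pow[ch, wi, ] + Mod(sp[bins])^2 / u
      }
    }
  }
  pow <- pow / d[1]
  # condition average first, then spectral neighbor normalization
  resp <- matrix(pow[, , 1] - (pow[, , 2] + pow[, , 3]) / 2, d[2], length(starts))
  bidx <- which(times >= baseline[1] & times <= baseline[2])
  if (!length(bidx)) stop("baseline window outside epoch", call. = FALSE)
  resp <- resp - rowMeans(resp[, bidx, drop = FALSE])
  tibble::tibble(
    channel = rep(trials$channels, times = length(times)),
    time = rep(times, each = d[2]),
    ssvep = as.vector(resp)
  )
}

#' Tidy a TFR into a long tibble
#' @param x a `tfr`
#' @param ... unused
#' @return tibble `trial`, `channel`, `freq`, `time`, `power`
#' @export
tidy.tfr <- function(x, ...) {
  d <- dim(x$power)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = prod(d[2:4])),
    channel = rep(rep(x$channels, each = d[1]), times = d[3] * d[4]),
    freq = rep(rep(x$freqs, each = d[1] * d[2]), times = d[4]),
    time = rep(x$times, each = prod(d[1:3])),
    power = as.vector(x$power)
  )
}
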