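fs <- 500

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

test_that("wavelet transform localizes frequency and scales with power", {
  tt <- (0:1999) / fs
  ts <- mk_trials(sin(2 * pi * 10 * tt), fs = fs)
  tfr <- morlet_tfr(ts, freqs = 2:15, step = 0.05)
  prof <- apply(tfr$power[1, 1, , ], 1, mean, na.rm = TRUE)
  expect_equal(tfr$freqs[which.max(prof)], 10)
  # every interior time point peaks at 10 Hz
  interior <- which(tfr$times > 0.6 & tfr$times < 2.4)
  peaks <- apply(tfr$power[1, 1, , interior], 2, which.max)
  expect_true(all(tfr$freqs[peaks] == 10))
  # doubling amplitude adds log10(4) to log power at the peak frequency
  ts2 <- mk_trials(2 * sin(2 * pi * 10 * tt), fs = fs)
  tfr2 <- morlet_tfr(ts2, freqs = 2:15, step = 0.05)
  d <- tfr2$power[1, 1, 9, interior] - tfr$power[1, 1, 9, interior]
  expect_equal(mean(d), log10(4), tolerance = 1e-6)
  # boundary error names the offending frequency
  expect_error(morlet_tfr(mk_trials(rnorm(300), fs = fs), freqs = c(1, 10)), "1")
})

test_that("chirp ridge increases monotonically in time", {
  tt <- (0:2499) / fs
  f_inst <- 5 + (15 - 5) * tt / max(tt) # analytic instantaneous frequency
  phase <- 2 * pi * cumsum(f_inst) / fs
  ts <- mk_trials(sin(phase), fs = fs)
  tfr <- morlet_tfr(ts, freqs = seq(3, 18, by = 0.5), step = 0.1)
  interior <- which(tfr$times > 0.8 & tfr$times < 4.2)
  ridge <- tfr$freqs[apply(tfr$power[1, 1, , interior], 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  # ridge tracks the analytic instantaneous frequency
  expect_lt(max(abs(ridge - f_inst[round(tfr$times[interior] * fs)])), 1.5)
})

test_that("multitaper gamma estimator is peaked, flat on noise, and validated", {
  tt <- (0:999) / fs
  arr <- array(NA_real_, c(2, 1, 1000))
  arr[1, 1, ] <- sin(2 * pi * 70 * tt)
  arr[2, 1, ] <- sin(2 * pi * 70 * tt)
  g <- multitaper_gamma(trial_set(arr, fs, t0 = -0.5))
  prof <- apply(g$power[1, 1, , ], 1, mean, na.rm = TRUE)
  expect_equal(g$freqs[which.max(prof)], 70)
  # white noise: flat band profile (max/min linear ratio below 1.5)
  flat <- mean(vapply(1:10, function(s) {
    arr <- with_seed_test(s, array(rnorm(2 * 2000), c(2, 1, 2000)))
    g <- multitaper_gamma(trial_set(arr, fs, t0 = 0))
    pr <- 10^apply(g$power[, 1, , ], 2, mean, na.rm = TRUE)
    max(pr) / min(pr)
  }, numeric(1)))
  expect_lt(flat, 1.5)
  # zero signal floors at a constant minimal log power
  z <- multitaper_gamma(mk_trials(list(numeric(1000), numeric(1000)), fs = fs))
  expect_true(all(is.finite(z$power)))
  expect_equal(sd(as.vector(z$power)), 0, tolerance = 1e-8)
  # taper count must respect the time-bandwidth product
  expect_error(
    multitaper_gamma(mk_trials(rnorm(1000), fs = fs), smoothing = 2),
    "tapers"
  )
})

test_that("gamma normalization zeroes the baseline and is scale-invariant", {
  set.seed(11)
  mk <- function(scale = 1) {
    xs <- lapply(1:8, function(i) {
      set.seed(100 + i)
      x <- rnorm(1500)
      step <- rep(c(1, 2), c(750, 750)) # amplitude step at stimulus onset
      scale * x * step
    })
    mk_trials(xs, fs = fs, t0 = -1.5)
  }
  g <- multitaper_gamma(mk())
  gn <- gamma_normalize(g, baseline = c(-0.7, -0.1))
  bidx <- which(gn$times >= -0.7 & gn$times <= -0.1)
  # condition-mean baseline is zero by construction
  expect_equal(mean(gn$power[, 1, , bidx]), 0, tolerance = 1e-10)
  # positive normalized gamma after the planted power step, every trial
  pidx <- which(gn$times > 0.3)
  post <- apply(gn$power[, 1, , pidx], 1, mean)
  expect_true(all(post > 0))
  # uniform rescaling of the raw signal leaves the output unchanged
  gn2 <- gamma_normalize(multitaper_gamma(mk(scale = 3)), baseline = c(-0.7, -0.1))
  expect_equal(gn$power, gn2$power, tolerance = 1e-8)
  # refuses to normalize twice
  expect_error(gamma_normalize(gn), "twice")
  # single-trial input has no across-trial SD
  g1 <- multitaper_gamma(mk_trials(rnorm(1500), fs = fs, t0 = -1.5))
  expect_error(gamma_normalize(g1), "2 trials")
})

test_that("spectral density integrates to the signal variance (Parseval)", {
  set.seed(21)
  x <- rnorm(1250)
  ts <- mk_trials(x, fs = fs)
  full_freqs <- seq(0, fs / 2, by = 1 / 2.5)
  psd <- welch_psd(ts,
    span = c(0, 2.5), freqs = full_freqs, pad_s = NULL,
    window = "rect", log10 = FALSE
  )
  # one-sided sum: double all interior bins
  w <- rep(2, length(psd$freqs))
  w[psd$freqs %in% c(0, fs / 2)] <- 1
  total <- sum(psd$power[1, ] * w) * psd$df
  expect_equal(total, var(x) * (length(x) - 1) / length(x), tolerance = 0.05 * var(x))
  # sinusoid peak dominates neighbors by >= 20x
  tt <- (0:1249) / fs
  psd_s <- welch_psd(mk_trials(sin(2 * pi * 10 * tt), fs = fs),
    span = c(0, 2.5), freqs = full_freqs, pad_s = NULL, log10 = FALSE
  )
  pk <- which.min(abs(psd_s$freqs - 10))
  expect_gt(psd_s$power[1, pk] / psd_s$power[1, pk + 3], 20)
  expect_error(welch_psd(ts, freqs = c(10, 400)), "Nyquist")
})

test_that("disjoint trial subsets of one process give matching spectra", {
  mk_half <- function(seed, trials) {
    mk_trials(lapply(seq_len(trials), function(i) {
      gen_aperiodic(1, 3, fs, seed = child_seed(seed, i))
    }), fs = fs)
  }
  p1 <- welch_psd(mk_half(1, 10), span = c(0, 3))
  p2 <- welch_psd(mk_half(2, 10), span = c(0, 3))
  expect_equal(mean(p1$power - p2$power), 0, tolerance = 0.05)
})

test_that("slope fit is exact on power laws and robust to the alpha peak", {
  freqs <- log_freqs(2, 64, 41)
  psd <- structure(
    list(
      power = matrix(log10(freqs^-1), 1), freqs = freqs, df = NA,
      log10 = TRUE, window = "hann", channels = "ch01", flags = "log10"
    ),
    class = "psd"
  )
  sf <- fit_slope(psd, exclude = list())
  expect_equal(sf$slope, -1, tolerance = 1e-12)
  expect_equal(sf$r_squared, 1, tolerance = 1e-12)
  # a large 10 Hz peak inside the exclusion band does not bias the fit
  peaky <- psd
  peaky$power[1, ] <- log10(freqs^-1 + 50 * exp(-(freqs - 10)^2 / 2))
  expect_lt(abs(fit_slope(peaky)$slope + 1), 0.05)
  # the same peak at 20 Hz (outside the exclusion band) does bias it
  off_band <- psd
  off_band$power[1, ] <- log10(freqs^-1 + 50 * exp(-(freqs - 20)^2 / 2))
  expect_gt(abs(fit_slope(off_band)$slope + 1), 0.1)
  # scale invariance: rescaling changes the intercept only
  scaled <- psd
  scaled$power <- psd$power + log10(7)
  expect_equal(fit_slope(scaled, exclude = list())$slope, sf$slope, tolerance = 1e-12)
  expect_error(fit_slope(psd, fit_range = c(2, 3)), "10 frequencies")
})

test_that("SSVEP estimate isolates the entrained 30 Hz response", {
  tt <- seq(-1, 4.25, by = 1 / fs)[-1]
  mk_set <- function(amp, chi = 1) {
    mk_trials(lapply(1:8, function(i) {
      bg <- gen_aperiodic(chi, 5.25, fs, seed = child_seed(50, i))
      bg + ifelse(tt >= 0 & tt <= 3, amp * sin(2 * pi * 30 * tt), 0)
    }), fs = fs, t0 = tt[1])
  }
  # pure broadband input: post-onset values near zero
  null_sv <- ssvep_estimate(mk_set(0))
  during <- null_sv$ssvep[null_sv$time > 0.7 & null_sv$time < 2.3]
  expect_lt(abs(mean(during)), 2 * sd(during) / sqrt(length(during)) + 0.05)
  # entrained stimulus: clearly positive during presentation
  sv <- ssvep_estimate(mk_set(0.8))
  expect_gt(mean(sv$ssvep[sv$time > 0.7 & sv$time < 2.3]), 10 * abs(mean(during)))
  expect_error(
    ssvep_estimate(mk_set(0.5), f0 = 30.3),
    "grid"
  )
})
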