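test_that("modulation index hits its exact bounds and the quadrature value", {
  set.seed(81)
  ph <- runif(5000, -pi, pi)
  expect_identical(as.numeric(pac_mi(ph, rep(1, 5000))), 0)
  expect_identical(as.numeric(pac_mi(rep(0.1, 200), runif(200))), 1)
  # dense sampling of envelope (1 + cos)/2 matches numeric bin integration
  phd <- seq(-pi, pi, length.out = 200001)[-1]
  mi <- as.numeric(pac_mi(phd, (1 + cos(phd)) / 2))
  edges <- seq(-pi, pi, length.out = 17)
  bm <- vapply(1:16, function(i) {
    integrate(function(x) (1 + cos(x)) / 2, edges[i], edges[i + 1])$value /
      (edges[i + 1] - edges[i])
  }, numeric(1))
  p <- bm / sum(bm)
  mi_oracle <- (log(16) + sum(p * log(p))) / log(16)
  expect_equal(mi, mi_oracle, tolerance = 1e-3)
})

test_that("modulation index is bounded and amplitude-scale invariant", {
  set.seed(82)
  for (i in 1:25) {
    ph <- runif(500, -pi, pi)
    amp <- rexp(500)^sample(1:3, 1)
    mi <- as.numeric(pac_mi(ph, amp))
    expect_gte(mi, 0)
    expect_lte(mi, 1)
    expect_equal(as.numeric(pac_mi(ph, amp * 123.4)), mi, tolerance = 1e-12)
  }
})

test_that("surrogate normalization is unbiased under independence", {
  set.seed(83)
  norm_mi <- vapply(1:20, function(s) {
    segs_ph <- lapply(1:10, function(i) runif(120, -pi, pi))
    segs_am <- lapply(1:10, function(i) rexp(120))
    raw <- as.numeric(pac_mi(unlist(segs_ph), unlist(segs_am)))
    sur <- surrogate_mi(segs_ph, segs_am, n_surrogates = 150, seed = s)
    raw - sur$mean
  }, numeric(1))
  expect_lt(abs(mean(norm_mi)), 2 * sd(norm_mi) / sqrt(length(norm_mi)))
  # determinism of the surrogate distribution
  segs_ph <- lapply(1:5, function(i) runif(100, -pi, pi))
  segs_am <- lapply(1:5, function(i) rexp(100))
  s1 <- surrogate_mi(segs_ph, segs_am, n_surrogates = 120, seed = 7)
  s2 <- surrogate_mi(segs_ph, segs_am, n_surrogates = 120, seed = 7)
  expect_identical(s1$dist, s2$dist)
  expect_error(surrogate_mi(segs_ph[1], segs_am[1], 100, seed = 1), ">= 2 segments")
  expect_warning(surrogate_mi(segs_ph, segs_am, n_surrogates = 50, seed = 1), "100")
})

test_that("identical duplicated segments defeat trial shuffling (blind spot)", {
  set.seed(84)
  ph <- runif(200, -pi, pi)
  amp <- (1 + cos(ph)) / 2 # perfectly coupled
  segs_ph <- rep(list(ph), 6)
  segs_am <- rep(list(amp), 6)
  raw <- as.numeric(pac_mi(unlist(segs_ph), unlist(segs_am)))
  sur <- surrogate_mi(segs_ph, segs_am, n_surrogates = 150, seed = 2)
  # shuffling identical segments cannot break the coupling
  expect_lt(abs(raw - sur$mean), 1e-12)
})

test_that("episode-locked coupling pipeline flags planted gamma coupling", {
  fs <- 500
  dur <- 12
  mk_pac_trial <- function(kappa, seed) {
    tt <- (seq_len(dur * fs) - 1) / fs
    phase <- 2 * pi * 10 * tt
    bg <- gen_aperiodic(1, dur, fs, seed = child_seed(seed, 1)) * 0.5
    alpha <- sin(phase)
    gam <- gen_pac(10, c(80, 150), kappa, dur, fs,
      seed = child_seed(seed, 2), phase = phase
    )
    bg + alpha + 1.5 * as.numeric(gam)
  }
  # onsets incommensurate with the 100 ms alpha period, so segments carry
  # different phase trajectories and shuffling can break the coupling
  onsets <- seq(0.8, 10.6, by = 0.97)
  eps <- mk_episodes(onsets, onsets + 0.4, span = c(0, dur), n_trials = 1)
  run <- function(kappa, control = FALSE) {
    ts <- mk_trials(mk_pac_trial(kappa, 4 + kappa * 10), fs = fs)
    pac_pipeline(ts, eps,
      amp_freqs = seq(60, 140, by = 20), control = control,
      n_surrogates = 150, seed = 5
    )
  }
  coupled <- run(0.8)
  expect_true(all(c("amp_freq", "mi_raw", "mi_norm") %in% names(coupled)))
  expect_true(all(coupled$mi_raw >= 0 & coupled$mi_raw <= 1))
  # normalized MI well above the surrogate spread inside the planted band
  in_band <- coupled$amp_freq >= 80 & coupled$amp_freq <= 140
  expect_gt(
    max(coupled$mi_norm[in_band] / coupled$mi_surrogate_sd[in_band]),
    3
  )
  uncoupled <- run(0)
  expect_lt(
    max(abs(uncoupled$mi_norm / uncoupled$mi_surrogate_sd)),
    4
  )
  expect_error(
    pac_pipeline(mk_trials(rnorm(6000)),
      mk_episodes(1, 1.4, span = c(0, 12)),
      amp_freqs = c(80, 100), n_surrogates = 100
    ),
    "10 episode segments"
  )
})

test_that("trough-locked averaging finds troughs at the carrier period", {
  fs <- 500
  tt <- (0:2999) / fs
  x <- cos(2 * pi * 10 * tt) + 0.05 * gen_aperiodic(1, 6, fs, seed = 2)
  ts <- mk_trials(x, fs = fs)
  eps <- mk_episodes(0.5, 5.5, span = c(0, 6), n_trials = 1)
  tl <- trough_locked_average(ts, eps)
  expect_gt(tl$n_troughs, 40)
  # one trough per carrier period (100 ms) inside the episode
  expect_lte(abs(tl$n_troughs - 50), 2)
  # raw average at lag zero is the trough (minimum) of the carrier
  expect_lt(tl$raw[which(tl$lag == 0)], min(tl$raw) + 0.1)
  # no-trough input returns an empty flagged result
  flat <- trough_locked_average(
    mk_trials(sin(2 * pi * 3 * (0:2999) / fs), fs = fs),
    mk_episodes(numeric(0), numeric(0), span = c(0, 6), n_trials = 1)
  )
  expect_identical(flat$n_troughs, 0L)
})
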