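test_that("aperiodic generator has the planted spectral exponent", {
  # white noise: fitted log-log slope near 0
  sl0 <- mean(vapply(1:6, function(s) {
    ts <- mk_trials(gen_aperiodic(0, 10, 500, seed = s))
    fit_slope(welch_psd(ts, span = c(0, 10), pad_s = NULL), exclude = list())$slope
  }, numeric(1)))
  expect_lt(abs(sl0), 0.05)
  # chi = 2: slope near -2 (independent OLS on the periodogram)
  sl2 <- mean(vapply(1:10, function(s) {
    ts <- mk_trials(gen_aperiodic(2, 10, 500, seed = s))
    fit_slope(welch_psd(ts, span = c(0, 10), pad_s = NULL), exclude = list())$slope
  }, numeric(1)))
  expect_lt(abs(sl2 + 2), 0.1)
  # normalization and determinism
  x <- gen_aperiodic(1, 4, 250, seed = 3)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_identical(x, gen_aperiodic(1, 4, 250, seed = 3))
  expect_error(gen_aperiodic(NA, 1, 100), "finite")
  expect_error(gen_aperiodic(-1, 1, 100), "non-negative")
})

test_that("burst generator honors abundance, taper and interval contracts", {
  z <- gen_bursts(10, 0, 10, 5, 500)
  expect_identical(z$signal, numeric(2500))
  expect_identical(nrow(z$intervals), 0L)
  # abundance 1: one continuous oscillation spanning the window
  full <- gen_bursts(10, 1, 2, 5, 500)
  expect_identical(nrow(full$intervals), 1L)
  expect_equal(full$intervals$offset - full$intervals$onset, 5)
  expect_gt(min(abs(range(full$signal))), 0.1)
  # occupied fraction tracks the target
  b <- gen_bursts(10, 0.5, 10, 10, 500, seed = 4)
  occupied <- sum(b$intervals$offset - b$intervals$onset)
  expect_equal(occupied / 10, 0.5, tolerance = 0.05)
  expect_true(all(b$intervals$offset - b$intervals$onset >= 3 / 10 - 1e-9))
  # a window too short for three cycles must error
  expect_error(gen_bursts(10, 0.05, 10, 2, 500), "3 cycles")
})

test_that("coupled-gamma generator plants phase-dependent amplitude", {
  env_by_phase <- function(kappa, seed) {
    x <- gen_pac(10, c(80, 150), kappa, 8, 500, seed = seed)
    ph <- ((attr(x, "phase") + pi) %% (2 * pi)) - pi
    env <- abs(x)
    as.numeric(pac_mi(ph, env^2))
  }
  mi_low <- mean(vapply(1:8, function(s) env_by_phase(0.2, s), numeric(1)))
  mi_high <- mean(vapply(1:8, function(s) env_by_phase(0.6, s), numeric(1)))
  expect_gt(mi_high, mi_low)
  # kappa = 1, preferred phase 0: binned envelope maximal at the phase-0 bin
  x1 <- gen_pac(10, c(80, 150), 1, 8, 500, seed = 1, preferred_phase = 0)
  ph <- ((attr(x1, "phase") + pi) %% (2 * pi)) - pi
  prof <- attr(pac_mi(ph, abs(x1)^2), "profile")
  centers <- seq(-pi, pi, length.out = 17)[-17] + pi / 16
  expect_lt(abs(centers[which.max(prof)]), pi / 8 + 1e-9)
  expect_error(gen_pac(10, c(80, 300), 0.5, 1, 500), "Nyquist|inside")
  expect_error(gen_pac(10, c(80, 150), 1.5, 1, 500), "kappa")
})

test_that("ground truth plants monotone trends scaled by the latent factor", {
  cfg <- study_config(n_subjects = 40, seed = 5)
  tr <- gen_truth(cfg, effect_spec())
  expect_true(all(tr$kappa >= 0 & tr$kappa <= 1))
  expect_true(all(tr$a > 0))
  expect_true(all(tr$t0 >= 0))
  expect_true(all(tr$alpha_abundance >= 0 & tr$alpha_abundance <= 1))
  # within-subject load slopes of the coupled fields scale with g
  slopes <- vapply(split(tr, tr$subject), function(d) {
    unname(coef(lm(d$v ~ d$load))[2])
  }, numeric(1))
  gs <- vapply(split(tr, tr$subject), function(d) d$g[1], numeric(1))
  # base drift slope is negative; larger g makes it more negative
  expect_lt(cor(gs, slopes), -0.5)
  chi_slopes <- vapply(split(tr, tr$subject), function(d) {
    unname(coef(lm(d$chi ~ d$load))[2])
  }, numeric(1))
  expect_lt(cor(gs, chi_slopes), -0.5)
})

test_that("study generation is seed-deterministic and subset-stable", {
  cfg <- study_config(n_subjects = 2, trials_per_load = 2, grid = c(2, 2), seed = 9)
  st1 <- gen_study(cfg)
  st2 <- gen_study(cfg)
  expect_identical(st1$signals, st2$signals)
  expect_identical(st1$behavior, st2$behavior)
  expect_identical(st1$truth, st2$truth)
  # regenerating only subject 2 reproduces its slice bit-identically
  sub <- gen_study(cfg, subjects = 2)
  expect_identical(
    st1$signals[["2"]][[3]]$data,
    sub$signals[["2"]][[3]]$data
  )
  expect_identical(
    st1$behavior[st1$behavior$subject == 2, ]$rt_s,
    sub$behavior$rt_s
  )
  expect_identical(
    st1$pupil[["2"]][[1]]$traces,
    sub$pupil[["2"]][[1]]$traces
  )
  # posterior channels carry the planted rhythms; frontal ones do not
  expect_setequal(cfg$posterior, c("ch02", "ch04"))
})

test_that("study bundle round-trips through the plain-text writer", {
  cfg <- study_config(n_subjects = 1, trials_per_load = 2, grid = c(2, 2), seed = 2)
  st <- gen_study(cfg, components = c("behavior"))
  path <- withr::local_tempdir()
  write_study(st, path)
  beh <- utils::read.csv(file.path(path, "behavior.csv"))
  expect_equal(nrow(beh), 2 * 4)
  expect_named(beh, c("subject", "load", "trial", "rt_s", "accuracy"))
  tru <- utils::read.csv(file.path(path, "truth.csv"))
  expect_equal(tru$v, st$truth$v, tolerance = 1e-12)
  expect_true(file.exists(file.path(path, "config.yaml")))
})

test_that("child seeds are deterministic, order-sensitive and in range", {
  expect_identical(child_seed(1, 2, 3), child_seed(1, 2, 3))
  expect_false(child_seed(1, 2, 3) == child_seed(1, 3, 2))
  seeds <- vapply(1:1000, function(k) child_seed(7, k), integer(1))
  expect_true(all(seeds >= 1 & seeds <= 2147483646))
  expect_gt(length(unique(seeds)), 990)
})
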