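test_that("diffusion simulation respects symmetry and strong-drift limits", {
  b0 <- ddm_simulate(ddm_params(0, 1.5, 0.3, p_outlier = 0), 4000,
    seed = 1, dt = 1e-3
  )
  expect_lt(abs(mean(b0$accuracy) - 0.5), 2 * sqrt(0.25 / 4000) + 0.02)
  # huge drift: immediate upper-bound absorption
  bfast <- ddm_simulate(ddm_params(10, 1, 0.3, p_outlier = 0), 1000,
    seed = 2, dt = 1e-4
  )
  expect_gt(mean(bfast$accuracy), 0.99)
  expect_lt(mean(bfast$rt_s), 0.3 + 0.15)
  expect_identical(
    ddm_simulate(ddm_params(1, 1.5, 0.3), 50, seed = 3, dt = 1e-3),
    ddm_simulate(ddm_params(1, 1.5, 0.3), 50, seed = 3, dt = 1e-3)
  )
})

test_that("first-passage density is a proper density matching the simulator", {
  v <- 1.5
  a <- 1.5
  f_up <- function(t) oscidyn:::wfpt_lower(t, -v, a)
  f_lo <- function(t) oscidyn:::wfpt_lower(t, v, a)
  # defect densities over both bounds integrate to one
  total <- integrate(function(t) f_up(t) + f_lo(t), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-4)
  # analytic absorption probability at the upper bound
  p_up <- integrate(f_up, 0, Inf, rel.tol = 1e-9)$value
  z <- a / 2
  expect_equal(p_up, (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a)), tolerance = 1e-6)
  # simulated correct-RT histogram matches the conditional density (chi^2 GOF)
  b <- ddm_simulate(ddm_params(v, a, 0.3, p_outlier = 0), 8000, seed = 5, dt = 1e-4)
  rt_c <- b$rt_s[b$accuracy == 1] - 0.3
  qs <- quantile(rt_c, seq(0.1, 0.9, by = 0.1))
  edges <- c(0, qs, Inf)
  obs <- table(cut(rt_c, edges))
  expected_p <- vapply(seq_len(length(edges) - 1), function(i) {
    integrate(f_up, edges[i], min(edges[i + 1], 50), rel.tol = 1e-8)$value
  }, numeric(1)) / p_up
  chisq <- sum((as.numeric(obs) - length(rt_c) * expected_p)^2 /
    (length(rt_c) * expected_p))
  expect_lt(chisq, qchisq(0.99, df = length(obs) - 1))
})

test_that("likelihood handles contamination, cutoffs and impossible RTs", {
  tab <- tibble::tibble(rt_s = c(0.2, 0.5, 0.9, 2.8), accuracy = c(1, 1, 0, 1))
  ll <- ddm_loglik(tab, ddm_params(1, 1.5, 0.3))
  expect_true(is.finite(ll))
  expect_identical(attr(ll, "n_excluded"), 1L) # the 0.2 s premature response
  # outlier mixture dominates the pure diffusion tail at extreme RTs
  pure <- ddm_loglik(
    tibble::tibble(rt_s = c(0.5, 9.9), accuracy = c(1, 1)),
    ddm_params(2, 1.5, 0.3, p_outlier = 0)
  )
  mixed <- ddm_loglik(
    tibble::tibble(rt_s = c(0.5, 9.9), accuracy = c(1, 1)),
    ddm_params(2, 1.5, 0.3, p_outlier = 0.05)
  )
  expect_gt(mixed, pure)
  # rt <= t0 without contamination is impossible
  bad <- ddm_loglik(
    tibble::tibble(rt_s = 0.26, accuracy = 1),
    ddm_params(1, 1.5, 0.4, p_outlier = 0)
  )
  expect_identical(as.numeric(bad), -Inf)
  expect_error(ddm_params(1, -1, 0.3), "positive")
  expect_error(ddm_params(1, 1, -0.1), "non-negative")
})

test_that("maximum likelihood recovers planted condition-wise parameters", {
  v <- c(2, 1.6, 1.2, 0.8)
  t0 <- c(0.3, 0.32, 0.35, 0.4)
  tab <- dplyr::bind_rows(lapply(1:4, function(l) {
    b <- ddm_simulate(ddm_params(v[l], 1.5, t0[l]), 256,
      seed = child_seed(91, l), dt = 1e-4
    )
    b$load <- l
    b
  }))
  fit <- ddm_fit(tab, "drift_ndt", seed = 1)
  expect_true(fit$converged)
  est <- fit$params
  expect_true(all(diff(est$v) < 0)) # monotone drift ordering recovered
  expect_lt(abs(est$a - 1.5) / 1.5, 0.15)
  expect_lt(max(abs(est$t0 - t0)), 0.06)
  expect_true(all(is.finite(tidy(fit)$se)))
  # information criteria prefer the generating structure over the null
  fit_null <- ddm_fit(tab, "null", seed = 1)
  expect_lt(fit$bic, fit_null$bic)
  cmp <- ddm_model_compare(list(fit, fit_null))
  expect_identical(cmp$variant[1], "drift_ndt")
  expect_identical(cmp$delta_bic[1], 0)
  # mismatched data refuse comparison
  other <- ddm_fit(tab[tab$load < 3, ], "null", seed = 1)
  expect_error(ddm_model_compare(list(fit, other)), "identical data")
})

test_that("drift estimate bias shrinks with trial count", {
  bias_at <- function(n) {
    reps <- vapply(1:3, function(s) {
      b <- ddm_simulate(ddm_params(1.5, 1.5, 0.3), n,
        seed = child_seed(93, n, s), dt = 2e-4
      )
      b$load <- 1
      fit <- ddm_fit(b, "null", seed = s)
      abs(fit$params$v - 1.5)
    }, numeric(1))
    mean(reps)
  }
  errs <- c(bias_at(64), bias_at(1024))
  expect_lt(errs[2], errs[1] + 0.05)
})

test_that("signature estimators return exact slopes on constructed ramps", {
  times <- seq(-0.6, 0.2, by = 0.002)
  ramp <- 3.2 * times
  est <- signature_slope(ramp, times)
  expect_equal(est$slope, 3.2, tolerance = 1e-9)
  const <- signature_slope(rep(2.5, length(times)), times)
  expect_equal(const$slope, 0, tolerance = 1e-9)
  expect_equal(const$amplitude, 2.5, tolerance = 1e-9)
  # unbiased under additive noise
  set.seed(7)
  ests <- vapply(1:60, function(i) {
    signature_slope(ramp + rnorm(length(times), 0, 0.3), times)$slope
  }, numeric(1))
  expect_lt(abs(mean(ests) - 3.2), 2 * sd(ests) / sqrt(60))
  expect_error(signature_slope(ramp, times, slope_window = c(-2, -1)), "outside")
  # planted drift-slope correlation across synthetic subjects is recovered
  set.seed(8)
  vs <- runif(15, 0.5, 2.5)
  slopes <- vapply(vs, function(v) {
    signature_slope(v * times + rnorm(length(times), 0, 0.2), times)$slope
  }, numeric(1))
  expect_gt(cor(vs, slopes), 0.5)
})
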