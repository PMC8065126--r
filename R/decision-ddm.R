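#' Drift-diffusion parameters
#'
#' Two-boundary diffusion with unit diffusion coefficient, symmetric start
#' point `a/2`, absorbing bounds at 0 and `a`; the upper bound codes the
#' correct response (accuracy coding). RT = first-passage time + `t0`.
#' A fixed fraction `p_outlier` of responses is contaminated with uniform
#' RTs.
#'
#' @param v drift rate (evidence units/s); scalar or one per condition
#' @param a boundary separation (> 0); scalar or one per condition
#' @param t0 non-decision time, seconds (>= 0); scalar or one per condition
#' @param p_outlier contamination probability (default 0.05)
#' @param rt_floor premature-response cutoff, seconds (default 0.25)
#' @return list of class `ddm_params`
#' @export
ddm_params <- function(v, a, t0, p_outlier = 0.05, rt_floor = 0.25) {
  if (any(a <= 0)) stop("`a` must be positive", call. = FALSE)
  if (any(t0 < 0)) stop("`t0` must be non-negative", call. = FALSE)
  if (p_outlier < 0 || p_outlier >= 0.5) stop("`p_outlier` must lie in [0, 0.5)", call. = FALSE)
  structure(list(v = v, a = a, t0 = t0, p_outlier = p_outlier, rt_floor = rt_floor),
    class = "ddm_params"
  )
}

#' Simulate the two-boundary drift-diffusion process
#'
#' Euler-Maruyama integration with step `dt` (default 0.1 ms), symmetric
#' start point, absorbing bounds at 0 and `a`. Upper-bound absorption codes
#' a correct response. A `p_outlier` fraction of trials is replaced with
#' uniform RTs over the observed range and random accuracy.
#'
#' @param params a [ddm_params()] with scalar `v`, `a`, `t0`
#' @param n_trials number of trials
#' @param seed integer seed
#' @param dt integration step, seconds
#' @param max_t give-up time, seconds
#' @return tibble: `trial`, `rt_s`, `accuracy`
#' @export
ddm_simulate <- function(params, n_trials, seed = 1, dt = 1e-4, max_t = 10) {
  stopifnot(inherits(params, "ddm_params"), n_trials >= 1)
  v <- params$v[1]
  a <- params$a[1]
  t0 <- params$t0[1]
  with_seed(seed, {
    x <- rep(a / 2, n_trials)
    rt <- rep(NA_real_, n_trials)
    acc <- rep(NA_integer_, n_trials)
    active <- seq_len(n_trials)
    sq <- sqrt(dt)
    block <- 2000L
    step0 <- 0L
    while (length(active) && step0 * dt < max_t) {
      k <- length(active)
      incr <- matrix(rnorm(block * k, mean = v * dt, sd = sq), block, k)
      paths <- apply(incr, 2, cumsum) + rep(x[active], each = block)
      if (k == 1) paths <- matrix(paths, ncol = 1)
      up <- paths >= a
      dn <- paths <= 0
      hit <- up | dn
      first <- apply(hit, 2, function(h) if (any(h)) which.max(h) else NA_integer_)
      done <- which(!is.na(first))
      for (j in done) {
        i <- active[j]
        s <- first[j]
        rt[i] <- (step0 + s) * dt + t0
        acc[i] <- as.integer(up[s, j])
      }
      if (length(done)) {
        x[active[-done]] <- paths[block, -done]
        active <- active[-done]
      } else {
        x[active] <- paths[block, ]
      }
      step0 <- step0 + block
    }
    # unabsorbed trials at max_t: assign boundary by position
    if (length(active)) {
      rt[active] <- max_t + t0
      acc[active] <- as.integer(x[active] >= a / 2)
    }
    if (params$p_outlier > 0) {
      n_out <- rbinom(1, n_trials, params$p_outlier)
      if (n_out > 0) {
        pick <- sample.int(n_trials, n_out)
        rt[pick] <- runif(n_out, min(rt), max(rt))
        acc[pick] <- rbinom(n_out, 1, 0.5)
      }
    }
    tibble::tibble(trial = seq_len(n_trials), rt_s = rt, accuracy = acc)
  })
}

# first-passage-time density at the LOWER bound of a Wiener diffusion with
# boundary separation a, relative start z, drift v, unit diffusion
# (Navarro & Fuss-style adaptive small-time / large-time series)
wfpt_lower <- function(t, v, a, z = 0.5, eps = 1e-10) {
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tt <- t[pos] / a^2 # normalized time
  # terms needed for each series at tolerance eps (adaptive truncation)
  ks <- ceiling(pmax(
    sqrt(tt) + 1,
    2 + sqrt(pmax(0, -2 * tt * log(2 * sqrt(2 * pi * tt) * eps)))
  ))
  ks[!is.finite(ks)] <- 2
  kl <- ceiling(pmax(
    1 / (pi * sqrt(tt)),
    sqrt(pmax(0, -2 * log(pi * tt * eps)) / (pi^2 * tt))
  ))
  kl[!is.finite(kl)] <- 1
  f <- numeric(length(tt))
  small <- ks < kl
  if (any(small)) {
    ts <- tt[small]
    kmax <- max(ks[small])
    acc <- numeric(length(ts))
    for (k in -kmax:kmax) {
      w <- z + 2 * k
      acc <- acc + w * exp(-w^2 / (2 * ts))
    }
    f[small] <- acc / sqrt(2 * pi * ts^3)
  }
  if (any(!small)) {
    tl <- tt[!small]
    kmax <- max(kl[!small])
    acc <- numeric(length(tl))
    for (k in seq_len(kmax)) {
      acc <- acc + k * exp(-k^2 * pi^2 * tl / 2) * sin(k * pi * z)
    }
    f[!small] <- pi * acc
  }
  out[pos] <- pmax(0, f * exp(-v * a * z - v^2 * t[pos] / 2) / a^2)
  out
}

#' Drift-diffusion likelihood of observed responses
#'
#' Joint density of RT and response under the symmetric-start two-boundary
#' diffusion, evaluated by the first-passage-time series expansion, mixed
#' with a uniform contamination density at weight `p_outlier`. Correct
#' responses are absorptions at the upper bound (density with drift `+v`),
#' errors at the lower bound.
#'
#' @param table tibble with `rt_s`, `accuracy` (and optionally `load` when
#'   `params` carries per-condition values; loads are matched by sorted order)
#' @param params a [ddm_params()]
#' @return log-likelihood (scalar); attribute `n_excluded` reports RTs at or
#'   below the premature cutoff that were excluded
#' @export
ddm_loglik <- function(table, params) {
  keep <- table$rt_s > params$rt_floor
  excl <- sum(!keep)
  table <- table[keep, , drop = FALSE]
  loads <- if ("load" %in% names(table)) sort(unique(table$load)) else 1
  expand <- function(p) if (length(p) == 1) rep(p, length(loads)) else p
  v <- expand(params$v)
  a <- expand(params$a)
  t0 <- expand(params$t0)
  stopifnot(length(v) == length(loads), length(a) == length(loads), length(t0) == length(loads))
  rng <- range(table$rt_s)
  unif_d <- if (diff(rng) > 0) 1 / diff(rng) else 1
  ll <- 0
  for (li in seq_along(loads)) {
    rows <- if ("load" %in% names(table)) table$load == loads[li] else rep(TRUE, nrow(table))
    rt <- table$rt_s[rows]
    acc <- table$accuracy[rows]
    tdec <- rt - t0[li]
    dens <- numeric(length(rt))
    up <- acc == 1
    # upper bound = lower bound of the sign-flipped process
    if (any(up)) dens[up] <- wfpt_lower(tdec[up], -v[li], a[li], 0.5)
    if (any(!up)) dens[!up] <- wfpt_lower(tdec[!up], v[li], a[li], 0.5)
    mix <- (1 - params$p_outlier) * dens + params$p_outlier * unif_d / 2
    if (any(mix <= 0)) {
      if (params$p_outlier == 0) {
        ll <- -Inf
        break
      }
      mix <- pmax(mix, .Machine$double.xmin)
    }
    ll <- ll + sum(log(mix))
  }
  attr(ll, "n_excluded") <- excl
  ll
}

ddm_variants <- c("full", "drift", "drift_threshold", "drift_ndt", "null")

variant_free <- function(variant) {
  switch(variant,
    full = c(v = TRUE, a = TRUE, t0 = TRUE),
    drift = c(v = TRUE, a = FALSE, t0 = FALSE),
    drift_threshold = c(v = TRUE, a = TRUE, t0 = FALSE),
    drift_ndt = c(v = TRUE, a = FALSE, t0 = TRUE),
    null = c(v = FALSE, a = FALSE, t0 = FALSE),
    stop("unknown model variant: ", variant, call. = FALSE)
  )
}

#' Fit drift-diffusion parameters by per-subject maximum likelihood
#'
#' Condition-wise parameters are freed according to the model variant
#' (`"full"`: drift, threshold and non-decision time all vary by condition;
#' `"drift"`, `"drift_threshold"`, `"drift_ndt"`: the named subsets vary;
#' `"null"`: all shared). Optimization uses `nlminb` with box constraints
#' and multiple start points; standard errors come from the observed
#' information (numerical Hessian).
#'
#' @param table tibble with `load`, `rt_s`, `accuracy` for one subject
#' @param variant one of `"full"`, `"drift"`, `"drift_threshold"`,
#'   `"drift_ndt"`, `"null"`
#' @param p_outlier contamination weight held fixed (default 0.05)
#' @param rt_floor premature cutoff, seconds
#' @param n_starts optimization restarts
#' @param seed integer seed for start-point jitter
#' @return object of class `ddm_fit`: estimates tibble, log-likelihood,
#'   AIC/BIC, convergence diagnostics
#' @export
ddm_fit <- function(table, variant = "full", p_outlier = 0.05,
                    rt_floor = 0.25, n_starts = 3, seed = 1) {
  variant <- match.arg(variant, ddm_variants)
  loads <- sort(unique(table$load))
  n_l <- length(loads)
  tab <- table[table$rt_s > rt_floor, , drop = FALSE]
  n_per <- table(tab$load)
  if (any(n_per < 40)) {
    warning("fewer than 40 usable trials in some condition; estimates may be unstable")
  }
  free <- variant_free(variant)
  n_rep <- function(f) if (f) n_l else 1
  build <- function(theta) {
    i <- 0
    take <- function(k) {
      out <- theta[(i + 1):(i + k)]
      i <<- i + k
      out
    }
    # evaluate eagerly: R's lazy argument evaluation must not reorder take()
    v_ <- take(n_rep(free["v"]))
    a_ <- take(n_rep(free["a"]))
    t0_ <- take(n_rep(free["t0"]))
    ddm_params(v = v_, a = a_, t0 = t0_, p_outlier = p_outlier, rt_floor = rt_floor)
  }
  nll <- function(theta) {
    p <- tryCatch(build(theta), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- ddm_loglik(tab, p)
    if (!is.finite(ll)) 1e10 else -as.numeric(ll)
  }
  # t0 cannot exceed the fastest genuine response; with contamination a few
  # uniform outliers may undercut t0, so bound by a low quantile per load
  t0_cap <- vapply(loads, function(l) {
    rt_l <- tab$rt_s[tab$load == l]
    if (p_outlier > 0) unname(quantile(rt_l, 0.05)) else min(rt_l)
  }, numeric(1))
  t0_up <- if (free["t0"]) t0_cap - 1e-3 else min(t0_cap) - 1e-3
  min_rt <- min(tab$rt_s)
  lower <- c(rep(-10, n_rep(free["v"])), rep(0.2, n_rep(free["a"])), rep(0.01, n_rep(free["t0"])))
  upper <- c(rep(10, n_rep(free["v"])), rep(6, n_rep(free["a"])), t0_up)
  # crude moment-based start: accuracy -> drift sign/size, rt spread -> a
  acc_bar <- max(0.55, min(0.98, mean(tab$accuracy)))
  v0 <- sign(acc_bar - 0.5) * 1
  a0 <- 1.5
  t00 <- max(0.05, min_rt * 0.8)
  start0 <- c(
    rep(v0, n_rep(free["v"])), rep(a0, n_rep(free["a"])),
    pmin(t00, t0_up)
  )
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      st <- if (s == 1) start0 else pmin(pmax(start0 * exp(rnorm(length(start0), 0, 0.25)), lower), upper)
      fit <- tryCatch(
        nlminb(st, nll, lower = lower, upper = upper,
          control = list(eval.max = 500, iter.max = 300)),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) best <- fit
    }
  })
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  theta <- best$par
  hess <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  se <- rep(NA_real_, length(theta))
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  k <- length(theta)
  n <- nrow(tab)
  ll <- -best$objective
  par_names <- c(
    if (free["v"]) paste0("v_", loads) else "v",
    if (free["a"]) paste0("a_", loads) else "a",
    if (free["t0"]) paste0("t0_", loads) else "t0"
  )
  structure(
    list(
      estimates = tibble::tibble(parameter = par_names, estimate = theta, se = se),
      params = build(theta),
      loglik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + log(n) * k,
      n_trials = n, n_excluded = sum(table$rt_s <= rt_floor),
      variant = variant, loads = loads,
      converged = best$convergence == 0,
      data_hash = sum(tab$rt_s) + sum(tab$accuracy) * pi
    ),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "<ddm_fit:%s> logLik %.2f, AIC %.1f, BIC %.1f, %d trials%s\n",
    x$variant, x$loglik, x$aic, x$bic, x$n_trials,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  print(x$estimates)
  invisible(x)
}

#' Tidy drift-diffusion estimates
#' @param x a `ddm_fit`
#' @param ... unused
#' @return tibble of parameter estimates and standard errors
#' @export
tidy.ddm_fit <- function(x, ...) x$estimates

#' One-line fit summary
#' @param x a `ddm_fit`
#' @param ... unused
#' @return one-row tibble: variant, loglik, AIC, BIC, trial counts
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, loglik = x$loglik, aic = x$aic, bic = x$bic,
    n_trials = x$n_trials, n_excluded = x$n_excluded, converged = x$converged
  )
}

#' Compare drift-diffusion model variants on the same data
#'
#' @param fits list of `ddm_fit` objects fitted to identical data
#' @param criterion `"bic"` (default) or `"aic"`
#' @return tibble sorted by criterion with a delta column
#' @export
ddm_model_compare <- function(fits, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  hashes <- vapply(fits, function(f) f$data_hash, numeric(1))
  if (max(hashes) - min(hashes) > 1e-6 * max(1, abs(hashes[1]))) {
    stop("fits were not computed on identical data", call. = FALSE)
  }
  tab <- purrr::map_dfr(fits, glance)
  tab <- dplyr::arrange(tab, .data[[criterion]])
  tab[[paste0("delta_", criterion)]] <- tab[[criterion]] - tab[[criterion]][1]
  tab
}
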