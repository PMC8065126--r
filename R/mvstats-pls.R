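new_pls_result <- function(u, v, s, p_perm, bsr, boot_se, scores,
                           kind, extra = list()) {
  structure(
    c(list(
      u = u, v = v, s = s,
      crossblock_pct = 100 * s^2 / sum(s^2),
      p_perm = p_perm, bsr = bsr, boot_se = boot_se,
      brain_scores = scores, kind = kind
    ), extra),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result:%s> %d latent variables\n", x$kind, length(x$s)))
  print(tibble::tibble(
    lv = seq_along(x$s), singular_value = x$s,
    crossblock_pct = x$crossblock_pct, p_perm = x$p_perm
  ))
  invisible(x)
}

#' Glance at a PLS solution
#' @param x a `pls_result`
#' @param ... unused
#' @return tibble with one row per latent variable
#' @export
glance.pls_result <- function(x, ...) {
  tibble::tibble(
    lv = seq_along(x$s), singular_value = x$s,
    crossblock_pct = x$crossblock_pct, p_perm = x$p_perm
  )
}

#' Tidy PLS feature weights
#' @param x a `pls_result`
#' @param lv latent variable index (default 1)
#' @param ... unused
#' @return tibble: `feature`, `weight` (V), `bsr`
#' @export
tidy.pls_result <- function(x, lv = 1, ...) {
  tibble::tibble(
    feature = rownames(x$v) %||% seq_len(nrow(x$v)),
    weight = x$v[, lv],
    bsr = x$bsr[, lv]
  )
}

# align a bootstrap/permutation SVD to the reference via Procrustes rotation
procrustes_align <- function(v_ref, v_new, s_new, u_new) {
  m <- t(v_ref) %*% v_new
  sv <- svd(m)
  q <- sv$v %*% t(sv$u) # rotation bringing new onto ref
  list(
    v = v_new %*% q,
    u = u_new %*% q,
    s = diag(t(q) %*% diag(s_new, nrow = length(s_new)) %*% q)
  )
}

pls_svd <- function(m) {
  sv <- svd(m) # m: condition/behavior x feature
  k <- min(dim(m))
  list(u = sv$u[, seq_len(k), drop = FALSE], s = sv$d[seq_len(k)],
       v = sv$v[, seq_len(k), drop = FALSE])
}

#' Task partial least squares
#'
#' Decomposes the condition x feature matrix of grand means (column-centered
#' across conditions) by SVD into condition weights `U`, singular values `S`
#' and feature ("brain") weights `V`. Latent-variable significance comes
#' from permuting condition labels within subject and re-decomposing;
#' feature robustness from bootstrap resampling of subjects (Procrustes
#' aligned), giving bootstrap ratios BSR = V / SE. Brain scores are the
#' subject x condition projections `V' P`.
#'
#' @param cube array `subject x condition x feature` (dimnames used when
#'   present)
#' @param n_perm permutations (default 1000)
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed integer seed
#' @return a `pls_result`
#' @export
task_pls <- function(cube, n_perm = 1000, n_boot = 1000, seed = 1) {
  d <- dim(cube)
  S <- d[1]
  C <- d[2]
  Fq <- d[3]
  if (C < 2) stop("need >= 2 conditions", call. = FALSE)
  if (S < 10) warning("fewer than 10 subjects: bootstrap estimates unstable")
  cond_means <- function(x) {
    m <- apply(x, c(2, 3), mean) # condition x feature
    sweep(m, 2, colMeans(m)) # grand-mean column centering
  }
  obs <- pls_svd(cond_means(cube))
  k <- length(obs$s)
  with_seed(seed, {
    perm_s <- matrix(NA_real_, n_perm, k)
    for (p in seq_len(n_perm)) {
      shuf <- cube
      for (s in seq_len(S)) shuf[s, , ] <- cube[s, sample.int(C), ]
      perm_s[p, ] <- pls_svd(cond_means(shuf))$s
    }
    p_perm <- vapply(seq_len(k), function(j) {
      (sum(perm_s[, j] >= obs$s[j]) + 1) / (n_perm + 1)
    }, numeric(1))
    boot_v <- array(NA_real_, c(Fq, k, n_boot))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(S, replace = TRUE)
      bs <- pls_svd(cond_means(cube[idx, , , drop = FALSE]))
      boot_v[, , b] <- procrustes_align(obs$v, bs$v, bs$s, bs$u)$v
    }
  })
  boot_se <- apply(boot_v, c(1, 2), sd)
  bsr <- obs$v / ifelse(boot_se > 0, boot_se, NA_real_)
  # brain scores: subject x condition per LV, list over LVs
  scores <- lapply(seq_len(k), function(j) {
    sc <- matrix(NA_real_, S, C)
    for (s in seq_len(S)) sc[s, ] <- cube[s, , ] %*% obs$v[, j]
    sc
  })
  rownames(obs$v) <- dimnames(cube)[[3]]
  new_pls_result(obs$u, obs$v, obs$s, p_perm, bsr, boot_se, scores, "task")
}

#' Behavioral partial least squares
#'
#' Decomposes the behavior x feature correlation matrix (column-wise Pearson
#' correlations across subjects) by SVD. Significance: singular values under
#' row-shuffling of the behavior block relative to the brain block.
#' Robustness: subject bootstrap with Procrustes alignment, yielding BSRs
#' for feature weights and percentile confidence intervals for the
#' behavior-side correlation loadings (correlations of each behavior
#' variable with the LV brain scores).
#'
#' @param brain matrix `subject x feature`
#' @param behavior matrix or tibble `subject x variable`
#' @param n_perm permutations
#' @param n_boot bootstrap resamples
#' @param seed integer seed
#' @param ci_level level for behavior-loading bootstrap intervals
#' @return a `pls_result` with `behavior_loadings` and their CIs
#' @export
behavioral_pls <- function(brain, behavior, n_perm = 1000, n_boot = 1000,
                           seed = 1, ci_level = 0.95) {
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  stopifnot(nrow(brain) == nrow(behavior))
  S <- nrow(brain)
  keep <- complete.cases(brain) & complete.cases(behavior)
  brain <- brain[keep, , drop = FALSE]
  behavior <- behavior[keep, , drop = FALSE]
  S <- nrow(brain)
  zv <- apply(behavior, 2, sd) == 0
  if (any(zv)) {
    stop("zero-variance behavior variable: ",
      paste(colnames(behavior)[zv], collapse = ", "),
      call. = FALSE
    )
  }
  corr_of <- function(br, be) cor(be, br) # behavior x feature
  obs <- pls_svd(corr_of(brain, behavior))
  k <- length(obs$s)
  brain_scores <- brain %*% obs$v # subject x LV
  behavior_loadings <- cor(behavior, brain_scores) # behavior x LV
  with_seed(seed, {
    perm_s <- matrix(NA_real_, n_perm, k)
    for (p in seq_len(n_perm)) {
      perm_s[p, ] <- pls_svd(corr_of(brain, behavior[sample.int(S), , drop = FALSE]))$s
    }
    p_perm <- vapply(seq_len(k), function(j) {
      (sum(perm_s[, j] >= obs$s[j]) + 1) / (n_perm + 1)
    }, numeric(1))
    boot_v <- array(NA_real_, c(ncol(brain), k, n_boot))
    boot_load <- array(NA_real_, c(ncol(behavior), k, n_boot))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(S, replace = TRUE)
      if (any(apply(behavior[idx, , drop = FALSE], 2, sd) == 0)) next
      bs <- pls_svd(corr_of(brain[idx, , drop = FALSE], behavior[idx, , drop = FALSE]))
      al <- procrustes_align(obs$v, bs$v, bs$s, bs$u)
      boot_v[, , b] <- al$v
      bsc <- brain[idx, , drop = FALSE] %*% al$v
      ok <- apply(bsc, 2, sd) > 0
      bl <- matrix(NA_real_, ncol(behavior), k)
      if (any(ok)) bl[, ok] <- cor(behavior[idx, , drop = FALSE], bsc[, ok, drop = FALSE])
      boot_load[, , b] <- bl
    }
  })
  boot_se <- apply(boot_v, c(1, 2), sd, na.rm = TRUE)
  bsr <- obs$v / ifelse(boot_se > 0, boot_se, NA_real_)
  alpha <- (1 - ci_level) / 2
  ci_lo <- apply(boot_load, c(1, 2), quantile, probs = alpha, na.rm = TRUE)
  ci_hi <- apply(boot_load, c(1, 2), quantile, probs = 1 - alpha, na.rm = TRUE)
  rownames(obs$v) <- colnames(brain)
  rownames(obs$u) <- colnames(behavior)
  new_pls_result(
    obs$u, obs$v, obs$s, p_perm, bsr, boot_se,
    scores = brain_scores, kind = "behavioral",
    extra = list(
      behavior_loadings = behavior_loadings,
      behavior_ci_lo = ci_lo, behavior_ci_hi = ci_hi
    )
  )
}
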