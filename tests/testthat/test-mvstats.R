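mk_long <- function(values) {
  # values: subject x load matrix
  tibble::tibble(
    subject = rep(seq_len(nrow(values)), times = ncol(values)),
    load = rep(seq_len(ncol(values)), each = nrow(values)),
    value = as.vector(values)
  )
}

test_that("first-level load betas and their group test behave exactly", {
  vals <- outer(rep(0, 6), 1:4, function(s, l) 2 * l)
  le <- load_betas(mk_long(vals))
  expect_true(all(abs(le$betas$beta - 2) < 1e-12))
  expect_lt(le$p, 1e-10)
  # permuted labels: betas centered at zero
  set.seed(61)
  null_means <- vapply(1:60, function(i) {
    load_betas(mk_long(matrix(rnorm(24), 6, 4)))$mean_beta
  }, numeric(1))
  expect_lt(abs(mean(null_means)), 3 * sd(null_means) / sqrt(60))
  expect_error(load_betas(mk_long(matrix(1, 2, 4))), "3 subjects")
  # pairwise comparisons carry BH-adjusted p-values
  expect_true(all(le$pairwise$p_adjusted >= le$pairwise$p_value - 1e-15))
})

test_that("BH adjustment matches the hand-computed step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  # never decreases any p-value
  set.seed(62)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("within-subject centering preserves condition means exactly", {
  set.seed(63)
  d <- tibble::tibble(
    subject = rep(1:8, each = 4),
    condition = rep(1:4, times = 8),
    value = rnorm(32, mean = rep(1:8, each = 4)) # big subject offsets
  )
  cd <- within_subject_center(d)
  # condition means conserved
  before <- tapply(d$value, d$condition, mean)
  after <- tapply(cd$value, cd$condition, mean)
  expect_equal(unname(after), unname(before), tolerance = 1e-12)
  # every subject mean equals the grand mean
  subj_means <- tapply(cd$value, cd$subject, mean)
  expect_equal(as.numeric(subj_means), rep(mean(d$value), 8), tolerance = 1e-12)
  # already-centered data: identity
  expect_equal(within_subject_center(cd)$value, cd$value, tolerance = 1e-12)
  expect_error(within_subject_center(d[-1, ]), "complete")
})

test_that("partial repeated-measures correlation isolates residual coupling", {
  # x2 equal to x1 minus subject and load means: perfect residual coupling
  set.seed(64)
  d <- tibble::tibble(
    subject = rep(1:10, each = 4),
    load = rep(1:4, times = 10),
    x1 = rnorm(40)
  )
  res <- residuals(lm(x1 ~ factor(subject) + factor(load), data = d))
  d$x2 <- as.numeric(res)
  r1 <- partial_rmcorr(d)
  expect_equal(r1$r, 1, tolerance = 1e-8)
  # planted residual coupling of known strength is recovered
  recovered <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    n_s <- 47
    shared <- rnorm(n_s * 4)
    dd <- tibble::tibble(
      subject = rep(seq_len(n_s), each = 4),
      load = rep(1:4, times = n_s),
      x1 = rep(rnorm(n_s), each = 4) + rep(0.3 * (1:4), n_s) +
        shared + rnorm(n_s * 4),
      x2 = rep(rnorm(n_s), each = 4) + rep(-0.2 * (1:4), n_s) +
        shared + rnorm(n_s * 4)
    )
    partial_rmcorr(dd)$r
  }, numeric(1))
  expect_lt(abs(median(recovered) - 0.5), 0.1)
  # collinear covariate errors out
  d$x3 <- as.numeric(d$load)
  expect_error(
    partial_rmcorr(dplyr::mutate(d, x2 = as.numeric(load))),
    "collinear"
  )
  # main-effect directions reported as signs
  r2 <- partial_rmcorr(tibble::tibble(
    subject = rep(1:6, each = 4), load = rep(1:4, 6),
    x1 = rep(1:4, 6) + rnorm(24, 0, 0.1),
    x2 = -rep(1:4, 6) + rnorm(24, 0, 0.1)
  ))
  expect_identical(r2$direction_x1, 1)
  expect_identical(r2$direction_x2, -1)
})

test_that("cluster permutation test enforces spatial rules and recovers effects", {
  nb <- grid_neighbors(4, 4)
  # planted effect on the posterior half is found with high mass
  set.seed(65)
  eff <- array(rnorm(12 * 16 * 10), c(12, 16, 10))
  post <- which(rep(1:4, times = 4) > 2)
  eff[, post, 4:7] <- eff[, post, 4:7] + 1.2
  cr <- cluster_perm_test(eff, nb, n_perm = 500, seed = 1)
  td <- tidy(cr)
  expect_gte(nrow(td), 1)
  best <- td[which.min(td$p), ]
  expect_lt(best$p, 0.025)
  members <- cr$clusters$members[[which.min(td$p)]]
  expect_gte(length(intersect(unique(members$channel), post)), length(post) / 2)
  # an effect confined to two adjacent channels cannot form a cluster
  # (all other channels identically zero, hence t = 0 there)
  eff2 <- array(0, c(12, 16, 6))
  eff2[, c(1, 2), ] <- 5 + rnorm(12 * 2 * 6, sd = 0.1)
  cr2 <- cluster_perm_test(eff2, nb, n_perm = 200, seed = 2)
  expect_identical(nrow(tidy(cr2)), 0L)
  # p-values never undercut the permutation resolution
  expect_true(all(tidy(cr)$p >= 1 / 501))
  # map must cover the data and be connected
  expect_error(cluster_perm_test(eff, nb[1:4, 1:4], n_perm = 100), "cover")
  nb_disc <- nb
  nb_disc[5, ] <- FALSE
  nb_disc[, 5] <- FALSE
  expect_error(cluster_perm_test(eff, nb_disc, n_perm = 100), "disconnected")
})
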