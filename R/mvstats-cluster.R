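#' Grid channel layout and neighbor map
#'
#' Channels laid out on an `nrow x ncol` grid with 8-connectivity, the
#' layout the synthetic studies use. Returns a logical adjacency matrix.
#'
#' @param nrow,ncol grid dimensions
#' @return logical `channel x channel` adjacency matrix with channel labels
#' @export
grid_neighbors <- function(nrow = 4, ncol = 4) {
  n <- nrow * ncol
  pos <- cbind(rep(seq_len(nrow), times = ncol), rep(seq_len(ncol), each = nrow))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- abs(sweep(pos, 2, pos[i, ]))
    adj[i, ] <- d[, 1] <= 1 & d[, 2] <= 1
  }
  diag(adj) <- FALSE
  labs <- sprintf("ch%02d", seq_len(n))
  dimnames(adj) <- list(labs, labs)
  adj
}

# adjacency list over (channel, time) points: spatial neighbors at the same
# time point, temporal neighbors at the same channel
point_adjacency <- function(n_ch, n_t, neighbors) {
  pid <- function(ch, t) (t - 1L) * n_ch + ch
  adj <- vector("list", n_ch * n_t)
  nb_list <- lapply(seq_len(n_ch), function(ch) which(neighbors[ch, ]))
  for (t in seq_len(n_t)) {
    for (ch in seq_len(n_ch)) {
      p <- pid(ch, t)
      nbs <- pid(nb_list[[ch]], t)
      if (t > 1) nbs <- c(nbs, pid(ch, t - 1L))
      if (t < n_t) nbs <- c(nbs, pid(ch, t + 1L))
      adj[[p]] <- nbs
    }
  }
  adj
}

# connected components among supra-threshold points; returns per-cluster
# member lists, filtered by the minimum-channel rule
find_clusters <- function(supra, adj, ch_of_point, min_channels) {
  lab <- integer(length(supra))
  out <- list()
  for (p in which(supra)) {
    if (lab[p] != 0L) next
    id <- length(out) + 1L
    members <- integer(0)
    queue <- p
    lab[p] <- id
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, q)
      for (nb in adj[[q]]) {
        if (supra[nb] && lab[nb] == 0L) {
          lab[nb] <- id
          queue <- c(queue, nb)
        }
      }
    }
    if (length(unique(ch_of_point[members])) >= min_channels) {
      out[[length(out) + 1]] <- members
    }
  }
  out
}

max_cluster_mass <- function(tvec, thr, adj, ch_of_point, min_channels) {
  best <- 0
  for (sgn in c(1, -1)) {
    supra <- sgn * tvec > thr
    if (!any(supra)) next
    cl <- find_clusters(supra, adj, ch_of_point, min_channels)
    for (m in cl) best <- max(best, abs(sum(tvec[m])))
  }
  best
}

#' Cluster-based permutation test over channels and time
#'
#' First-level statistic per point is the one-sample t over subjects of the
#' supplied per-subject effects (e.g. load-regression betas or condition
#' differences). Points exceeding the two-sided entry threshold
#' (`p < entry_p`) form clusters by spatio-temporal adjacency, with the
#' constraint that a cluster covers at least `min_channels` neighboring
#' channels. The cluster statistic is the summed t value; its null
#' distribution comes from sign-flipping the subject effect maps
#' (valid for symmetric paired designs) and recording the maximal cluster
#' mass per permutation. Cluster significance is conventionally read at
#' p < 0.025 per sign (two-sided).
#'
#' @param effects array `subject x channel x time` (time may be a singleton)
#'   of per-subject effect estimates
#' @param neighbors logical channel adjacency matrix, e.g. [grid_neighbors()]
#' @param n_perm Monte-Carlo permutations (default 1000)
#' @param entry_p two-sided point-level entry threshold
#' @param min_channels minimum neighboring channels per cluster
#' @param seed integer seed
#' @return list of class `cluster_result`: `clusters` tibble (mass, p,
#'   member points), `t_map`, `max_null` distribution
#' @export
cluster_perm_test <- function(effects, neighbors, n_perm = 1000,
                              entry_p = 0.05, min_channels = 3, seed = 1) {
  if (length(dim(effects)) == 2) {
    effects <- array(effects, c(dim(effects), 1))
  }
  d <- dim(effects)
  S <- d[1]
  n_ch <- d[2]
  n_t <- d[3]
  if (S < 5) stop("need >= 5 subjects", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  if (nrow(neighbors) != n_ch) stop("neighbor map does not cover all channels", call. = FALSE)
  if (n_ch > 1 && any(rowSums(neighbors) == 0)) {
    stop("neighbor map contains disconnected channels", call. = FALSE)
  }
  X <- matrix(effects, S, n_ch * n_t) # subject x point
  thr <- qt(1 - entry_p / 2, df = S - 1)
  ss <- colSums(X^2)
  t_of <- function(sums) {
    mns <- sums / S
    vr <- pmax(ss - S * mns^2, 0) / (S - 1)
    mns / sqrt(vr / S + .Machine$double.xmin)
  }
  t_obs <- t_of(colSums(X))
  adj <- point_adjacency(n_ch, n_t, neighbors)
  ch_of_point <- rep(seq_len(n_ch), times = n_t)
  min_ch_eff <- min(min_channels, n_ch)
  obs_clusters <- list()
  for (sgn in c(1, -1)) {
    supra <- sgn * t_obs > thr
    if (!any(supra)) next
    for (m in find_clusters(supra, adj, ch_of_point, min_ch_eff)) {
      obs_clusters[[length(obs_clusters) + 1]] <- list(members = m, sign = sgn)
    }
  }
  signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S))
  sums <- signs %*% X
  max_null <- vapply(seq_len(n_perm), function(i) {
    max_cluster_mass(t_of(sums[i, ]), thr, adj, ch_of_point, min_ch_eff)
  }, numeric(1))
  empty_clusters <- tibble::tibble(
    cluster = integer(), sign = numeric(), mass = numeric(),
    n_points = integer(), n_channels = integer(), p = numeric(),
    members = list()
  )
  clusters <- purrr::map_dfr(seq_along(obs_clusters), function(i) {
    m <- obs_clusters[[i]]$members
    mass <- sum(t_obs[m])
    tibble::tibble(
      cluster = i,
      sign = obs_clusters[[i]]$sign,
      mass = mass,
      n_points = length(m),
      n_channels = length(unique(ch_of_point[m])),
      p = (sum(max_null >= abs(mass)) + 1) / (n_perm + 1),
      members = list(tibble::tibble(
        channel = ch_of_point[m],
        time_index = (m - 1L) %/% n_ch + 1L
      ))
    )
  })
  if (!nrow(clusters)) clusters <- empty_clusters
  structure(
    list(
      clusters = clusters,
      t_map = matrix(t_obs, n_ch, n_t),
      entry_threshold = thr,
      max_null = max_null,
      n_perm = n_perm,
      min_channels = min_ch_eff
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s), %d permutations, entry |t| > %.2f\n",
    nrow(x$clusters), x$n_perm, x$entry_threshold
  ))
  if (nrow(x$clusters)) {
    print(dplyr::select(x$clusters, -"members"))
  }
  invisible(x)
}

#' Tidy cluster-test results
#' @param x a `cluster_result`
#' @param ... unused
#' @return tibble of clusters without the member lists
#' @export
tidy.cluster_result <- function(x, ...) dplyr::select(x$clusters, -"members")
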