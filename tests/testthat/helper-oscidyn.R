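# small builders shared across tests

# trial_set from a list of per-trial single-channel vectors
mk_trials <- function(xs, fs = 500, t0 = 0) {
  if (is.numeric(xs)) xs <- list(xs)
  n <- length(xs[[1]])
  arr <- array(NA_real_, c(length(xs), 1, n))
  for (i in seq_along(xs)) arr[i, 1, ] <- xs[[i]]
  trial_set(arr, fs, t0 = t0)
}

# multichannel trial_set: data[[trial]][[channel]] vectors
mk_trials_mc <- function(data, fs = 500, t0 = 0) {
  nt <- length(data)
  nc <- length(data[[1]])
  n <- length(data[[1]][[1]])
  arr <- array(NA_real_, c(nt, nc, n))
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) arr[tr, ch, ] <- data[[tr]][[ch]]
  }
  trial_set(arr, fs, t0 = t0)
}

# brute-force O(N^2) sample-entropy oracle (Chebyshev distance, pooled SD),
# independent of the compiled path
sampen_brute <- function(x, m = 2, r = 0.5) {
  rr <- r * sd(x)
  n <- length(x)
  nt <- n - m # extendable templates
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= rr) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= rr) A <- A + 1L
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# planted-burst detection scores for one seed
burst_detection_scores <- function(seed, abundance = 0.5, snr = 10,
                                   dur = 10, fs = 500) {
  bg <- gen_aperiodic(1, dur, fs, seed = child_seed(seed, 1))
  b <- gen_bursts(10, abundance, snr, dur, fs, seed = child_seed(seed, 2))
  ts <- mk_trials(bg + b$signal, fs = fs)
  tfr <- morlet_tfr(ts, log_freqs(1, 64, 49), cycles = 5, step = 0.01)
  bgf <- fit_background(tfr)
  eps <- detect_episodes(tfr, bgf, span = c(0.2, dur - 0.2))
  ea <- eps[eps$mean_freq >= 8 & eps$mean_freq <= 15, ]
  tt <- seq(0.2, dur - 0.2, by = 1 / fs)
  truth <- rep(FALSE, length(tt))
  det <- truth
  for (i in seq_len(nrow(b$intervals))) {
    truth <- truth | (tt >= b$intervals$onset[i] & tt <= b$intervals$offset[i])
  }
  for (i in seq_len(nrow(ea))) {
    det <- det | (tt >= ea$onset[i] & tt <= ea$offset[i])
  }
  c(
    recall = sum(det & truth) / max(1, sum(truth)),
    precision = sum(det & truth) / max(1, sum(det))
  )
}

# fabricate an episode_set (e.g. for PAC tests) without running detection
mk_episodes <- function(onsets, offsets, channel = "ch01", trial = 1,
                        mean_freq = 10, span = c(0, max(offsets)),
                        n_trials = max(trial)) {
  out <- tibble::tibble(
    trial = trial, channel = channel, onset = onsets, offset = offsets,
    mean_freq = mean_freq,
    cycles = (offsets - onsets) * mean_freq, snr = 10
  )
  attr(out, "span") <- span
  attr(out, "n_trials") <- n_trials
  class(out) <- c("episode_set", class(out))
  out
}
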