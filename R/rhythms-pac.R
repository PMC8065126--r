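#' Phase-amplitude modulation index via normalized entropy
#'
#' The amplitude (power) series is averaged within 16 uniform phase bins
#' over `(-pi, pi]`, the bin means are normalized to sum to one, and the
#' modulation index is the normalized entropy deficit
#' \eqn{MI = (\ln N - H) / \ln N}: 0 for a phase-independent amplitude,
#' 1 when all amplitude concentrates in a single bin. Empty bins contribute
#' zero mass (0 ln 0 := 0) and are flagged.
#'
#' @param phase radians in `(-pi, pi]`
#' @param amp_power non-negative amplitude/power series, same length
#' @param n_bins number of phase bins (default 16)
#' @return MI in `[0, 1]`; attributes `profile` (normalized bin means) and
#'   `empty_bins`
#' @export
#' @examples
#' ph <- runif(5000, -pi, pi)
#' pac_mi(ph, rep(1, 5000)) # 0: uniform
pac_mi <- function(phase, amp_power, n_bins = 16) {
  stopifnot(length(phase) == length(amp_power))
  if (any(amp_power < 0)) stop("`amp_power` must be non-negative", call. = FALSE)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(phase, edges, left.open = TRUE, all.inside = TRUE)
  means <- rep(0, n_bins)
  agg <- tapply(amp_power, factor(bin, levels = seq_len(n_bins)), mean)
  means[!is.na(agg)] <- agg[!is.na(agg)]
  tot <- sum(means)
  if (tot == 0) {
    mi <- 0
    prof <- rep(1 / n_bins, n_bins)
  } else {
    prof <- means / tot
    h <- -sum(ifelse(prof > 0, prof * log(prof), 0))
    mi <- (log(n_bins) - h) / log(n_bins)
  }
  attr(mi, "profile") <- prof
  attr(mi, "empty_bins") <- sum(is.na(agg))
  mi
}

#' Surrogate distribution of the modulation index by segment shuffling
#'
#' Each surrogate permutes which segment's amplitude series is paired with
#' which segment's phase series (identity permutation excluded, derangements
#' preferred), destroying within-segment phase-amplitude alignment while
#' preserving both marginals. Series are trimmed to the shorter member of
#' each shuffled pair.
#'
#' @param phase_segs list of phase vectors (radians)
#' @param amp_segs list of matching amplitude/power vectors
#' @param n_surrogates number of shuffles (default 1000)
#' @param n_bins phase bins for the MI
#' @param seed integer seed
#' @return list: `mean`, `sd`, `dist` (length `n_surrogates`)
#' @export
surrogate_mi <- function(phase_segs, amp_segs, n_surrogates = 1000,
                         n_bins = 16, seed = 1) {
  k <- length(phase_segs)
  stopifnot(length(amp_segs) == k)
  if (k < 2) stop("need >= 2 segments to shuffle", call. = FALSE)
  if (n_surrogates < 2) stop("need >= 2 surrogates", call. = FALSE)
  if (n_surrogates < 100) {
    warning("fewer than 100 surrogates: normalization will be noisy")
  }
  dist <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      repeat {
        perm <- sample.int(k)
        if (!all(perm == seq_len(k))) break
      }
      ph <- numeric(0)
      am <- numeric(0)
      for (i in seq_len(k)) {
        n <- min(length(phase_segs[[i]]), length(amp_segs[[perm[i]]]))
        ph <- c(ph, phase_segs[[i]][seq_len(n)])
        am <- c(am, amp_segs[[perm[i]]][seq_len(n)])
      }
      as.numeric(pac_mi(ph, am, n_bins))
    }, numeric(1))
  })
  list(mean = mean(dist), sd = sd(dist), dist = dist)
}

fir_bandpass <- function(x, fs, lo, hi, order = NULL) {
  # linear-phase FIR band-pass applied forward and backward (zero phase);
  # order rule: three times fs / low cutoff
  order <- order %||% round(3 * fs / lo)
  if (order %% 2 == 1) order <- order + 1
  b <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(b, x) # Ma method: zero-phase forward-backward pass
}

#' Alpha-phase to gamma-amplitude coupling spectrum over rhythmic episodes
#'
#' Implements the episode-locked coupling analysis: the alpha carrier phase
#' comes from a zero-phase 8-15 Hz band-pass plus Hilbert transform; the
#' amplitude bank band-passes 40-150 Hz (configurable step) with adaptive
#' bandwidths of +/-20% of the center frequency, z-scores each narrowband
#' signal, and squares the Hilbert magnitude for instantaneous power.
#' Analysis segments are the 250 ms following each episode onset (or, for
#' the control, the 250 ms preceding it); filter edges are trimmed by
#' 250 ms. Per amplitude frequency the raw MI on the concatenated segments
#' is normalized by subtracting the mean MI of segment-shuffled surrogates.
#'
#' @param trials a [trial_set()] (single channel selections already applied)
#' @param episodes an `episode_set` restricted to the alpha band; only
#'   episodes of the channels present in `trials` are used
#' @param amp_freqs center frequencies of the amplitude bank, Hz
#' @param phase_band carrier band, Hz
#' @param segment_s segment length after episode onset, seconds
#' @param control analyze pre-onset instead of post-onset segments
#' @param n_surrogates surrogate count for normalization
#' @param edge_s filter-edge trim, seconds
#' @param seed integer seed
#' @return tibble of class `pac_spectrum`: `amp_freq`, `mi_raw`,
#'   `mi_surrogate_mean`, `mi_surrogate_sd`, `mi_norm`, `n_segments`
#' @export
pac_pipeline <- function(trials, episodes,
                         amp_freqs = seq(40, 150, by = 2),
                         phase_band = c(8, 15), segment_s = 0.25,
                         control = FALSE, n_surrogates = 1000,
                         edge_s = 0.25, seed = 1) {
  fs <- trials$fs
  if (max(amp_freqs) * 1.2 >= fs / 2) {
    stop("amplitude band exceeds Nyquist after bandwidth expansion", call. = FALSE)
  }
  d <- dim(trials$data)
  nt <- d[3]
  keep_idx <- (round(edge_s * fs) + 1L):(nt - round(edge_s * fs))
  times_k <- trials$times[keep_idx]
  seg_n <- round(segment_s * fs)
  # collect (trial, onset-sample) segment anchors
  ep <- episodes[episodes$channel %in% trials$channels, , drop = FALSE]
  anchors <- list()
  for (i in seq_len(nrow(ep))) {
    ch <- match(ep$channel[i], trials$channels)
    t_on <- if (control) ep$onset[i] - segment_s else ep$onset[i]
    i0 <- which.min(abs(times_k - t_on))
    if (times_k[i0] - t_on > 1 / fs) next
    if (i0 + seg_n - 1L > length(keep_idx)) next
    anchors[[length(anchors) + 1]] <- c(ep$trial[i], ch, i0)
  }
  if (length(anchors) < 10) {
    stop("fewer than 10 episode segments pooled; not enough data for PAC", call. = FALSE)
  }
  anc <- do.call(rbind, anchors)
  # phase and amplitude series per needed trial x channel
  cells <- unique(anc[, 1:2, drop = FALSE])
  phase_store <- list()
  amp_store <- list()
  for (r in seq_len(nrow(cells))) {
    tr <- cells[r, 1]
    ch <- cells[r, 2]
    x <- trials$data[tr, ch, ]
    ph <- Arg(analytic_signal(fir_bandpass(x, fs, phase_band[1], phase_band[2])))[keep_idx]
    amps <- matrix(NA_real_, length(amp_freqs), length(keep_idx))
    for (fi in seq_along(amp_freqs)) {
      f <- amp_freqs[fi]
      nb <- fir_bandpass(x, fs, f * 0.8, min(f * 1.2, fs / 2 * 0.99))
      nb <- (nb - mean(nb)) / sd(nb)
      amps[fi, ] <- Mod(analytic_signal(nb))[keep_idx]^2
    }
    key <- paste(tr, ch)
    phase_store[[key]] <- ph
    amp_store[[key]] <- amps
  }
  out <- purrr::map_dfr(seq_along(amp_freqs), function(fi) {
    ph_segs <- list()
    am_segs <- list()
    for (r in seq_len(nrow(anc))) {
      key <- paste(anc[r, 1], anc[r, 2])
      idx <- anc[r, 3]:(anc[r, 3] + seg_n - 1L)
      ph_segs[[r]] <- phase_store[[key]][idx]
      am_segs[[r]] <- amp_store[[key]][fi, idx]
    }
    mi_raw <- as.numeric(pac_mi(unlist(ph_segs), unlist(am_segs)))
    sur <- surrogate_mi(ph_segs, am_segs,
      n_surrogates = n_surrogates,
      seed = child_seed(seed, fi)
    )
    tibble::tibble(
      amp_freq = amp_freqs[fi], mi_raw = mi_raw,
      mi_surrogate_mean = sur$mean, mi_surrogate_sd = sur$sd,
      mi_norm = mi_raw - sur$mean, n_segments = nrow(anc)
    )
  })
  class(out) <- c("pac_spectrum", class(out))
  out
}

#' Trough-locked average of high-frequency power and raw signal
#'
#' Alpha troughs are local minima of the carrier phase below
#' `-pi + 0.01` within detected episodes. The band-averaged high-frequency
#' power envelope (default 80-150 Hz) and the unfiltered trace are averaged
#' across troughs, time-locked to the trough sample.
#'
#' @param trials a [trial_set()]
#' @param episodes alpha-band `episode_set`
#' @param amp_band averaging band, Hz
#' @param phase_band carrier band, Hz
#' @param half_window_s window around each trough, seconds
#' @return list with `lag` (seconds), `envelope`, `raw`, `n_troughs`;
#'   `n_troughs = 0` yields empty vectors
#' @export
trough_locked_average <- function(trials, episodes, amp_band = c(80, 150),
                                  phase_band = c(8, 15),
                                  half_window_s = 0.15) {
  fs <- trials$fs
  hw <- round(half_window_s * fs)
  env_sum <- numeric(2 * hw + 1)
  raw_sum <- numeric(2 * hw + 1)
  n_tr <- 0L
  ep <- episodes[episodes$channel %in% trials$channels, , drop = FALSE]
  cells <- unique(ep[, c("trial", "channel")])
  for (r in seq_len(nrow(cells))) {
    tr <- cells$trial[r]
    ch <- match(cells$channel[r], trials$channels)
    x <- trials$data[tr, ch, ]
    ph <- Arg(analytic_signal(fir_bandpass(x, fs, phase_band[1], phase_band[2])))
    nb <- fir_bandpass(x, fs, amp_band[1], amp_band[2])
    env <- Mod(analytic_signal(nb))^2
    # troughs: local minima of the wrapped phase just past the -pi wrap; the
    # admission margin scales with how far the phase can advance per sample
    margin <- 2 * pi * phase_band[2] / fs + 0.01
    cand <- which(ph < -pi + margin)
    cand <- cand[cand > 1 & cand < length(ph)]
    cand <- cand[ph[cand] <= ph[cand - 1] & ph[cand] <= ph[cand + 1]]
    e_rows <- ep[ep$trial == tr & ep$channel == cells$channel[r], , drop = FALSE]
    for (tk in cand) {
      t_s <- trials$times[tk]
      if (!any(t_s >= e_rows$onset & t_s <= e_rows$offset)) next
      if (tk - hw < 1 || tk + hw > length(x)) next
      idx <- (tk - hw):(tk + hw)
      env_sum <- env_sum + env[idx]
      raw_sum <- raw_sum + x[idx]
      n_tr <- n_tr + 1L
    }
  }
  if (n_tr == 0L) {
    return(list(lag = numeric(), envelope = numeric(), raw = numeric(), n_troughs = 0L))
  }
  list(
    lag = (-hw:hw) / fs,
    envelope = env_sum / n_tr,
    raw = raw_sum / n_tr,
    n_troughs = n_tr
  )
}
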