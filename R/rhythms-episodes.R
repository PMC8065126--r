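#' Fit the aperiodic background of a wavelet spectrum and derive power
#' thresholds for episode detection
#'
#' Per channel, log10 wavelet power (5-cycle transform on 49 log-spaced
#' frequencies in 1-64 Hz) is averaged over trials and time and regressed on
#' log10 frequency, excluding the dominant alpha peak range (8-15 Hz) and
#' the 28-32 Hz range (the entrained stimulation response). The episode
#' power threshold at each frequency is the 95th percentile of the
#' exponential (chi-square with 2 df) power distribution implied by the
#' fitted background mean.
#'
#' @param tfr a `tfr` from [morlet_tfr()] with `cycles = 5` on the 1-64 Hz
#'   log grid
#' @param exclude list of Hz ranges excluded from the background fit
#' @param threshold_pct percentile of the background power distribution
#' @return object of class `background_fit`: per-channel intercept/slope,
#'   background and threshold power per frequency (linear units)
#' @export
fit_background <- function(tfr, exclude = list(c(8, 15), c(28, 32)),
                           threshold_pct = 0.95) {
  freqs <- tfr$freqs
  keep <- rep(TRUE, length(freqs))
  for (ex in exclude) keep <- keep & !(freqs >= ex[1] & freqs <= ex[2])
  if (sum(keep) < 10) stop("exclusions leave fewer than 10 fit frequencies", call. = FALSE)
  d <- dim(tfr$power)
  lf <- log10(freqs)
  # mean log10 power over trials and valid time points, per channel x freq
  mp <- apply(tfr$power, c(2, 3), mean, na.rm = TRUE)
  if (!tfr$log10) mp <- log10(mp)
  coefs <- t(vapply(seq_len(d[2]), function(ch) {
    coef(lm(mp[ch, keep] ~ lf[keep]))
  }, numeric(2)))
  bg_power <- 10^(coefs[, 1, drop = FALSE] %*% t(rep(1, length(freqs))) +
    coefs[, 2, drop = FALSE] %*% t(lf))
  # wavelet power of Gaussian noise is exponential about its mean:
  # chisq(2)/2 scaling of the fitted background mean
  mult <- qchisq(threshold_pct, df = 2) / 2
  structure(
    list(
      freqs = freqs, channels = tfr$channels,
      intercept = coefs[, 1], slope = coefs[, 2],
      background = bg_power, threshold = bg_power * mult,
      excluded = exclude, threshold_pct = threshold_pct
    ),
    class = "background_fit"
  )
}

#' Detect single-trial rhythmic episodes
#'
#' Time-frequency points whose linear wavelet power exceeds the
#' background-derived threshold are grouped into contiguous supra-threshold
#' regions (adjacent in time and frequency); each region is traced along its
#' per-column power ridge. Episodes whose duration is shorter than
#' `min_cycles` cycles of their (power-weighted) mean frequency are
#' discarded, as are episodes outside the analysis window (default: the
#' stimulus period excluding its first 500 ms).
#'
#' Because the wavelet smears power in time (Gaussian envelope with
#' \eqn{\sigma_t = cycles/(2\pi f)}), a detected run extends beyond the true
#' rhythmic event. Each per-frequency run is therefore trimmed by an
#' SNR-adaptive edge correction: a step edge convolved with the Gaussian
#' envelope stays supra-threshold for
#' \eqn{\sigma_t \Phi^{-1}(1 - \sqrt{thr/peak})} beyond the edge, and that
#' length (scaled by `edge_trim_sigma`, calibrated at 0.85) is removed from
#' both ends before runs are grouped. The three-cycle duration criterion is
#' judged on the dominant-frequency run of each group.
#'
#' @param tfr the same `tfr` used for [fit_background()]
#' @param bg a `background_fit`
#' @param min_cycles duration criterion in cycles (default 3)
#' @param span analysis window in seconds
#' @param edge_trim_sigma wavelet-smear edge correction, in units of the
#'   wavelet time SD (0 disables)
#' @return tibble of class `episode_set`: `trial`, `channel`, `onset`,
#'   `offset`, `mean_freq`, `cycles`, `snr`
#' @export
detect_episodes <- function(tfr, bg, min_cycles = 3, span = c(0.5, 3),
                            edge_trim_sigma = 0.85) {
  d <- dim(tfr$power)
  tidx <- which(tfr$times >= span[1] & tfr$times <= span[2])
  times <- tfr$times[tidx]
  freqs <- tfr$freqs
  dt <- if (length(times) > 1) times[2] - times[1] else 0
  rows <- list()
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      p <- tfr$power[tr, ch, , tidx, drop = TRUE]
      if (tfr$log10) p <- 10^p
      thr <- bg$threshold[ch, ]
      mask <- sweep(p, 1, thr, ">")
      mask[is.na(mask)] <- FALSE
      # per-frequency SNR-adaptive edge correction; trimming also severs
      # spurious bridges between adjacent true events
      if (edge_trim_sigma > 0 && dt > 0) {
        for (fi in seq_along(freqs)) {
          if (!any(mask[fi, ])) next
          sigma_t <- (tfr$cycles %||% 5) / (2 * pi * freqs[fi])
          r <- rle(mask[fi, ])
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          row <- rep(FALSE, ncol(mask))
          for (k in which(r$values)) {
            peak <- max(p[fi, starts[k]:ends[k]])
            # a step edge convolved with the Gaussian wavelet envelope stays
            # supra-threshold while amplitude Phi(-d/sigma) > sqrt(thr/peak)
            smear <- sigma_t * max(0, qnorm(1 - sqrt(thr[fi] / peak)))
            trim_cols <- round(edge_trim_sigma * smear / dt)
            s <- starts[k] + trim_cols
            e <- ends[k] - trim_cols
            if (e >= s) row[s:e] <- TRUE
          }
          mask[fi, ] <- row
        }
      }
      if (!any(mask)) next
      comp <- label_components(mask)
      for (id in seq_len(attr(comp, "n"))) {
        pts <- which(comp == id, arr.ind = TRUE)
        tcols <- sort(unique(pts[, 2]))
        # ridge: per time column, the supra-threshold frequency of max power
        ridge_f <- vapply(tcols, function(tc) {
          fr <- pts[pts[, 2] == tc, 1]
          fr[which.max(p[fr, tc])]
        }, numeric(1))
        ridge_pow <- vapply(seq_along(tcols), function(i) {
          p[ridge_f[i], tcols[i]]
        }, numeric(1))
        mean_freq <- sum(freqs[ridge_f] * ridge_pow) / sum(ridge_pow)
        # the duration criterion is judged on the dominant-frequency run:
        # the union over neighboring bins inflates duration by extreme-value
        # jitter, the single best-supported bin does not
        dom_fi <- pts[which.max(p[pts]), 1]
        cols_dom <- pts[pts[, 1] == dom_fi, 2]
        dom_cyc <- (max(cols_dom) - min(cols_dom) + 1) * dt * freqs[dom_fi]
        if (dom_cyc < min_cycles) next
        # reported extent follows the dominant-frequency run
        onset <- times[min(cols_dom)]
        offset <- times[max(cols_dom)] + dt
        cyc <- (offset - onset) * mean_freq
        if (cyc < min_cycles) next
        fi <- which.min(abs(freqs - mean_freq))
        rows[[length(rows) + 1]] <- tibble::tibble(
          trial = tr, channel = tfr$channels[ch],
          onset = onset, offset = offset,
          mean_freq = mean_freq, cycles = cyc,
          snr = mean(ridge_pow) / bg$background[ch, fi]
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(
      trial = integer(), channel = character(), onset = numeric(),
      offset = numeric(), mean_freq = numeric(), cycles = numeric(),
      snr = numeric()
    )
  }
  attr(out, "span") <- span
  attr(out, "n_trials") <- d[1]
  class(out) <- c("episode_set", class(out))
  out
}

# label 8-connected components of a logical matrix (freq x time)
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% nr + 1L
      c <- (q - 1L) %/% nr + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr
          cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          j <- (cc - 1L) * nr + rr
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  attr(lab, "n") <- cur
  lab
}

#' Summarize rhythmic episodes within a frequency band
#'
#' Trial-averaged abundance (fraction of the analysis window occupied by
#' episodes whose mean frequency falls in `band`) and mean episode SNR.
#' Trials without episodes contribute zero abundance.
#'
#' @param episodes an `episode_set` from [detect_episodes()]
#' @param band length-2 Hz range (e.g. `c(8, 15)` for alpha)
#' @return tibble: `channel`, `abundance`, `mean_snr`, `n_episodes`
#' @export
summarize_band_episodes <- function(episodes, band = c(8, 15)) {
  if (band[2] <= band[1]) stop("empty frequency band", call. = FALSE)
  span <- attr(episodes, "span")
  n_trials <- attr(episodes, "n_trials")
  win_len <- span[2] - span[1]
  channels <- unique(episodes$channel)
  eb <- dplyr::filter(episodes, .data$mean_freq >= band[1], .data$mean_freq <= band[2])
  if (!length(channels)) {
    return(tibble::tibble(
      channel = character(), abundance = numeric(),
      mean_snr = numeric(), n_episodes = integer()
    ))
  }
  purrr::map_dfr(channels, function(ch) {
    e <- dplyr::filter(eb, .data$channel == ch)
    # per-trial total episode duration; absent trials count as zero
    dur <- numeric(n_trials)
    if (nrow(e)) {
      agg <- dplyr::summarise(dplyr::group_by(e, .data$trial),
        d = sum(pmin(.data$offset, span[2]) - pmax(.data$onset, span[1])),
        .groups = "drop"
      )
      dur[agg$trial] <- agg$d
    }
    tibble::tibble(
      channel = ch,
      abundance = mean(dur) / win_len,
      mean_snr = if (nrow(e)) mean(e$snr) else NA_real_,
      n_episodes = nrow(e)
    )
  })
}
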