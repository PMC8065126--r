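#' Construct a pupil trace set
#'
#' @param traces matrix `trial x time` of pupil diameter (arbitrary units)
#' @param fs sampling rate, Hz
#' @param t0 time of the first sample relative to stimulus onset, seconds
#' @param blink_mask optional logical matrix marking vendor-indicated blinks
#' @param flags processing flags
#' @return object of class `pupil_set`
#' @export
pupil_set <- function(traces, fs, t0 = -1, blink_mask = NULL,
                      flags = character()) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (is.null(blink_mask)) blink_mask <- matrix(FALSE, nrow(traces), ncol(traces))
  stopifnot(all(dim(blink_mask) == dim(traces)))
  structure(
    list(
      traces = traces, fs = fs,
      times = t0 + (seq_len(ncol(traces)) - 1) / fs,
      blink_mask = blink_mask,
      interp_frac = rep(0, nrow(traces)),
      excluded = rep(FALSE, nrow(traces)),
      flags = flags
    ),
    class = "pupil_set"
  )
}

#' Clean pupil traces: outlier masking, padding, linear interpolation
#'
#' Outliers are samples where the z-standardized first derivative of the
#' auxiliary vertical-gaze series exceeds 3 SD, plus any vendor-indicated
#' blink samples. Masked spans are padded by 150 ms on each side and
#' linearly interpolated between the nearest valid neighbors (held constant
#' at trace edges). Trials with more than half their samples interpolated
#' are flagged excluded. Cleaning is idempotent: a second pass finds no new
#' outliers.
#'
#' @param raw a [pupil_set()]
#' @param gaze matrix `trial x time` of vertical gaze position aligned with
#'   the traces; `NULL` uses only the blink mask
#' @param z_cutoff outlier threshold in SD of the gaze derivative
#' @param pad_s padding around masked spans, seconds
#' @param max_interp trials interpolated beyond this fraction are excluded
#' @return a cleaned `pupil_set` with `interp_frac` and `excluded` filled in
#' @export
clean_pupil <- function(raw, gaze = NULL, z_cutoff = 3, pad_s = 0.15,
                        max_interp = 0.5) {
  n_tr <- nrow(raw$traces)
  nt <- ncol(raw$traces)
  pad <- round(pad_s * raw$fs)
  out <- raw
  for (tr in seq_len(n_tr)) {
    mask <- raw$blink_mask[tr, ]
    if (!is.null(gaze)) {
      dg <- diff(gaze[tr, ])
      z <- (dg - mean(dg)) / max(sd(dg), .Machine$double.eps)
      bad <- which(abs(z) >= z_cutoff)
      mask[unique(c(bad, bad + 1L))] <- TRUE
    }
    if (any(mask)) {
      idx <- which(mask)
      padded <- unique(unlist(lapply(idx, function(i) {
        max(1L, i - pad):min(nt, i + pad)
      })))
      mask[padded] <- TRUE
      good <- which(!mask)
      if (length(good) < 2) {
        out$excluded[tr] <- TRUE
        out$interp_frac[tr] <- 1
        next
      }
      out$traces[tr, ] <- approx(
        x = good, y = raw$traces[tr, good],
        xout = seq_len(nt), rule = 2
      )$y
      out$interp_frac[tr] <- mean(mask)
      out$excluded[tr] <- out$interp_frac[tr] > max_interp
    }
  }
  out$flags <- union(out$flags, "cleaned")
  out
}

#' First temporal derivative of pupil traces at 200 Hz
#'
#' Traces are low-pass filtered below the target Nyquist (zero-phase FFT
#' filter), resampled onto the 200 Hz grid, then differentiated (first
#' difference times the sampling rate). An
#' optional 200 ms running-median smoothing is available for display but is
#' deliberately not part of the statistical path.
#'
#' @param clean a cleaned [pupil_set()]
#' @param target_fs output sampling rate, Hz (default 200)
#' @param smooth apply the display-only running median
#' @return a `pupil_set` of derivative traces (units/s), flagged
#'   `"derivative"`
#' @export
phasic_derivative <- function(clean, target_fs = 200, smooth = FALSE) {
  if (!"cleaned" %in% clean$flags) {
    warning("derivative requested on traces not passed through clean_pupil()")
  }
  if (clean$fs < target_fs) stop("input sampling rate below target rate", call. = FALSE)
  out <- clean
  if (clean$fs != target_fs) {
    # anti-alias low-pass just below the target Nyquist, then resample onto
    # the coarser grid (pupil signals carry no power near either Nyquist)
    cutoff <- 0.45 * target_fs
    new_times <- seq(clean$times[1], clean$times[length(clean$times)],
      by = 1 / target_fs
    )
    res <- t(apply(clean$traces, 1, function(x) {
      mu <- mean(x)
      lp <- fft_bandpass(x - mu, clean$fs, 0, cutoff) + mu
      approx(clean$times, lp, xout = new_times, rule = 2)$y
    }))
    out$traces <- res
    out$fs <- target_fs
    out$times <- new_times
    out$blink_mask <- matrix(FALSE, nrow(res), ncol(res))
  }
  d <- t(apply(out$traces, 1, function(x) c(diff(x), NA) * out$fs))
  if (smooth) {
    w <- max(1L, round(0.2 * out$fs))
    d <- t(apply(d, 1, function(x) stats::runmed(ifelse(is.na(x), 0, x), 1 + 2 * (w %/% 2))))
    out$flags <- union(out$flags, "smoothed-display-only")
  }
  out$traces <- d
  out$flags <- union(out$flags, "derivative")
  out
}

#' Phasic arousal scalar: median pupil derivative in an early window
#'
#' Median of the derivative trace within `window` (default the first 1.5 s
#' after stimulus onset) per trial, averaged over non-excluded trials.
#'
#' @param deriv a `pupil_set` from [phasic_derivative()]
#' @param window length-2 seconds relative to stimulus onset
#' @return scalar; attribute `per_trial` holds the trial values
#' @export
extract_phasic <- function(deriv, window = c(0, 1.5)) {
  if (!"derivative" %in% deriv$flags) {
    stop("extract_phasic() expects derivative traces", call. = FALSE)
  }
  idx <- time_index(deriv$times, window)
  if (!length(idx)) stop("window outside epoch", call. = FALSE)
  per_trial <- apply(deriv$traces[, idx, drop = FALSE], 1, median, na.rm = TRUE)
  keep <- !deriv$excluded
  out <- mean(per_trial[keep])
  attr(out, "per_trial") <- per_trial
  attr(out, "n_used") <- sum(keep)
  out
}
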