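#' Entropy estimation parameters
#'
#' @param m template (sequence) length, default 2
#' @param r similarity criterion as a fraction of the pooled segment SD,
#'   default 0.5
#' @param window_s sliding-window length in seconds, default 0.5
#' @param step_s window step in seconds, default 0.15
#' @return a list of class `entropy_params`
#' @export
entropy_params <- function(m = 2, r = 0.5, window_s = 0.5, step_s = 0.15) {
  stopifnot(m >= 1, window_s >= step_s)
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  structure(list(m = as.integer(m), r = r, window_s = window_s, step_s = step_s),
    class = "entropy_params"
  )
}

#' Band-stop (notch) the alpha band before entropy estimation
#'
#' Zero-phase sixth-order Butterworth band-stop over 8-15 Hz, applied per
#' trial and channel, so narrowband posterior alpha rhythms do not dominate
#' the irregularity estimate. Adds the `"alpha_removed"` provenance flag that
#' [time_resolved_entropy()] requires.
#'
#' @param trials a [trial_set()]
#' @param band length-2 Hz stop band
#' @param order filter order (default 6)
#' @return a filtered [trial_set()]
#' @export
bandstop_alpha <- function(trials, band = c(8, 15), order = 6) {
  fs <- trials$fs
  if (band[2] >= fs / 2) stop("stop band must lie below Nyquist", call. = FALSE)
  nt <- length(trials$times)
  if (nt < 3 * order * 10) {
    stop("epoch too short for the filter to settle", call. = FALSE)
  }
  bf <- signal::butter(order / 2, band / (fs / 2), type = "stop")
  # filtfilt doubles the effective order: order/2 forward + backward = order
  d <- dim(trials$data)
  out <- trials$data
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out[tr, ch, ] <- signal::filtfilt(bf, trials$data[tr, ch, ])
    }
  }
  res <- trials
  res$data <- out
  add_flag(res, "alpha_removed")
}

#' Sample entropy across (possibly discontinuous) segments
#'
#' \eqn{SampEn(m, r, N) = -\ln(A/B)} where `B` counts template pairs of
#' length `m` within tolerance `r` (Chebyshev distance) and `A` the subset
#' that still match when extended to `m + 1`. Templates are counted within
#' segments only (none spans a boundary) but pairs may straddle segments, so
#' short windows pooled across trials still yield stable estimates.
#' `r` is interpreted relative to the SD pooled over all provided segments.
#' Self-matches are excluded. When no template pair matches (`B = 0`) the
#' estimate is undefined and `NA` is returned, never 0.
#'
#' @param segments a numeric vector or list of numeric vectors sampled at a
#'   common rate
#' @param params an [entropy_params()]
#' @return a double (nats) with attributes `A`, `B`, `n_templates`
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500))
sample_entropy <- function(segments, params = entropy_params()) {
  if (!inherits(params, "entropy_params")) stop("`params` must be entropy_params()", call. = FALSE)
  if (is.numeric(segments)) segments <- list(segments)
  lens <- lengths(segments)
  segments <- segments[lens > params$m] # too-short segments contribute nothing
  lens <- lengths(segments)
  x <- unlist(segments, use.names = FALSE)
  if (length(x) < params$m + 2) {
    stop("pooled sample count must be at least m + 2", call. = FALSE)
  }
  pooled_sd <- sd(x)
  if (pooled_sd == 0) {
    # constant signal: every template matches, conditional probability 1
    res <- 0
    attr(res, "A") <- attr(res, "B") <- Inf
    return(res)
  }
  cm <- count_matches(x, cumsum(lens), params$m, params$r * pooled_sd)
  res <- if (cm$B == 0 || cm$A == 0) NA_real_ else -log(cm$A / cm$B)
  attr(res, "A") <- cm$A
  attr(res, "B") <- cm$B
  attr(res, "n_templates") <- cm$n_templates
  res
}

#' Time-resolved sample entropy pooled across trials
#'
#' For each channel and half-open window `[t, t + window)` stepped along the
#' epoch, that window's samples from every trial form the discontinuous
#' segments entering one sample-entropy estimate. Because the similarity
#' criterion scales with the pooled within-window SD, the estimate is
#' implicitly variance-normalized and no temporal baseline is applied.
#' Requires the `"alpha_removed"` provenance flag set by [bandstop_alpha()].
#'
#' @param trials a [trial_set()] that has passed through [bandstop_alpha()]
#' @param params an [entropy_params()]
#' @param span length-2 analysis span in seconds (window onsets)
#' @return tibble: `channel`, `time` (window onset), `sampen`, `n_templates`
#' @export
time_resolved_entropy <- function(trials, params = entropy_params(),
                                  span = c(-1, 1.25)) {
  if (!has_flag(trials, "alpha_removed")) {
    stop("trials must pass through bandstop_alpha() first (alpha_removed flag missing)",
      call. = FALSE
    )
  }
  fs <- trials$fs
  win_n <- round(params$window_s * fs)
  onsets <- seq(
    max(span[1], trials$times[1]),
    min(span[2], trials$times[length(trials$times)] - params$window_s),
    by = params$step_s
  )
  d <- dim(trials$data)
  out <- purrr::map_dfr(seq_len(d[2]), function(ch) {
    purrr::map_dfr(onsets, function(t0) {
      i0 <- which.min(abs(trials$times - t0))
      idx <- i0:min(i0 + win_n - 1L, d[3])
      segs <- lapply(seq_len(d[1]), function(tr) trials$data[tr, ch, idx])
      se <- sample_entropy(segs, params)
      tibble::tibble(
        channel = trials$channels[ch], time = t0,
        sampen = as.numeric(se),
        n_templates = attr(se, "n_templates") %||% NA_integer_
      )
    })
  })
  attr(out, "params") <- params
  out
}
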