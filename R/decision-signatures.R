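#' Windowed slope and amplitude of a decision-signature waveform
#'
#' Estimates the two standard summaries of ramping decision signals
#' (centro-parietal positivity, contralateral mu-beta): the least-squares
#' slope of the trial-averaged waveform over a pre-response window (a proxy
#' of evidence drift rate) and the mean amplitude over a window around the
#' response (a proxy of the decision threshold). An optional low-pass filter
#' and condition-specific baseline are applied first, in that order.
#'
#' @param erp numeric vector: trial-averaged waveform for one channel
#'   (or channel average)
#' @param times time axis, seconds (response- or stimulus-locked)
#' @param slope_window length-2 window for the slope regression, seconds
#' @param amp_window length-2 window for the mean amplitude, seconds
#' @param baseline optional length-2 window subtracted as the mean baseline
#' @param lowpass_hz optional low-pass corner (sixth-order Butterworth,
#'   zero-phase); `NULL` to skip
#' @param fs sampling rate, needed when `lowpass_hz` is given
#' @return one-row tibble: `slope` (units/s), `amplitude`, window metadata
#' @export
signature_slope <- function(erp, times, slope_window = c(-0.25, -0.1),
                            amp_window = c(-0.05, 0.05), baseline = NULL,
                            lowpass_hz = NULL, fs = NULL) {
  stopifnot(length(erp) == length(times))
  check_win <- function(w, nm) {
    if (w[1] < times[1] - 1e-9 || w[2] > times[length(times)] + 1e-9) {
      stop(nm, " window lies outside the epoch", call. = FALSE)
    }
  }
  check_win(slope_window, "slope")
  check_win(amp_window, "amplitude")
  x <- erp
  if (!is.null(lowpass_hz)) {
    if (is.null(fs)) stop("`fs` required for filtering", call. = FALSE)
    bf <- signal::butter(3, lowpass_hz / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  if (!is.null(baseline)) {
    check_win(baseline, "baseline")
    bidx <- time_index(times, baseline)
    x <- x - mean(x[bidx])
  }
  sidx <- time_index(times, slope_window)
  fit <- lm(x[sidx] ~ times[sidx])
  aidx <- time_index(times, amp_window)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    amplitude = mean(x[aidx]),
    slope_window_lo = slope_window[1], slope_window_hi = slope_window[2],
    amp_window_lo = amp_window[1], amp_window_hi = amp_window[2],
    baselined = !is.null(baseline)
  )
}
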