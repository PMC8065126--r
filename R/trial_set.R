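#' Construct a trial set
#'
#' The common container for epoched multichannel signals: a numeric array of
#' `trial x channel x time` samples with a sampling rate and a time axis
#' relative to stimulus onset. Processing steps append provenance flags so
#' that downstream contracts (e.g. "alpha removed before entropy") can be
#' enforced, and a step refuses to run twice on its own output.
#'
#' @param data numeric array `trial x channel x time`
#' @param fs sampling rate in Hz
#' @param t0 time of the first sample in seconds relative to stimulus onset
#' @param channels character vector of channel labels (default `ch01`...)
#' @param flags character vector of processing flags
#' @return an object of class `trial_set`
#' @export
trial_set <- function(data, fs, t0 = 0, channels = NULL, flags = character()) {
  if (length(dim(data)) == 2) {
    data <- array(data, c(1, dim(data)))
  }
  stopifnot(length(dim(data)) == 3, fs > 0)
  n_ch <- dim(data)[2]
  channels <- channels %||% sprintf("ch%02d", seq_len(n_ch))
  stopifnot(length(channels) == n_ch)
  structure(
    list(
      data = data,
      fs = fs,
      times = t0 + (seq_len(dim(data)[3]) - 1) / fs,
      channels = channels,
      flags = flags
    ),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_set> %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$fs, x$times[1], x$times[length(x$times)]
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

n_trials <- function(ts) dim(ts$data)[1]

has_flag <- function(ts, flag) flag %in% ts$flags

add_flag <- function(ts, flag) {
  ts$flags <- union(ts$flags, flag)
  ts
}

time_index <- function(times, span) {
  which(times >= span[1] & times <= span[2] + 1e-12)
}

#' Tidy a trial set into a long tibble
#'
#' @param x a [trial_set()]
#' @param ... unused
#' @return a tibble with columns `trial`, `channel`, `time`, `value`
#' @export
tidy.trial_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
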