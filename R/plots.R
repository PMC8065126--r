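#' Plot a PAC spectrum
#'
#' Surrogate-normalized modulation index across amplitude frequencies.
#'
#' @param object a `pac_spectrum` from [pac_pipeline()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pac_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$amp_freq, y = .data$mi_norm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "amplitude frequency (Hz)",
      y = "surrogate-normalized MI"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the channel x time t-map of a cluster test
#'
#' @param object a `cluster_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.cluster_result <- function(object, ...) {
  tm <- object$t_map
  df <- tibble::tibble(
    channel = rep(seq_len(nrow(tm)), times = ncol(tm)),
    time_index = rep(seq_len(ncol(tm)), each = nrow(tm)),
    t = as.vector(tm)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_index, .data$channel, fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time index", y = "channel", fill = "t") +
    ggplot2::theme_minimal()
}

#' Plot latent-variable summaries of a PLS solution
#'
#' Crossblock covariance percentage per latent variable, annotated with the
#' permutation p-value.
#'
#' @param object a `pls_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pls_result <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$lv), .data$crossblock_pct)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("p = %.3f", .data$p_perm)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = "latent variable", y = "crossblock covariance (%)") +
    ggplot2::theme_minimal()
}

#' Plot load effects with within-subject centering
#'
#' Subject-wise condition profiles (centered for display) with the group
#' mean overlaid.
#'
#' @param data tibble with `subject`, `load`, `value`
#' @return a ggplot
#' @export
plot_load_profiles <- function(data) {
  centered <- within_subject_center(
    dplyr::rename(data, condition = "load")
  )
  ggplot2::ggplot(centered, ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1.2, colour = "red") +
    ggplot2::labs(x = "load", y = "value (within-subject centered)") +
    ggplot2::theme_minimal()
}
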