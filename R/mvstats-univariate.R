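#' First-level load slopes and their group test
#'
#' Per subject, the outcome is regressed on numeric load
#' (`y = intercept + beta * LOAD + e`, LOAD coded 1..K); the betas are
#' tested against zero with a two-sided one-sample t-test, and adjacent
#' conditions are compared with paired t-tests adjusted by the
#' Benjamini-Hochberg procedure.
#'
#' @param data tibble with columns `subject`, `load`, `value` (one value per
#'   subject x load; replicate rows are averaged first)
#' @return list of class `load_effect`: `betas` tibble, `t`, `df`, `p`,
#'   `pairwise` tibble
#' @export
load_betas <- function(data) {
  stopifnot(all(c("subject", "load", "value") %in% names(data)))
  cell <- dplyr::summarise(
    dplyr::group_by(data, .data$subject, .data$load),
    value = mean(.data$value), .groups = "drop"
  )
  loads <- sort(unique(cell$load))
  if (length(loads) < 2) stop("need >= 2 conditions", call. = FALSE)
  subjects <- unique(cell$subject)
  if (length(subjects) < 3) stop("need >= 3 subjects", call. = FALSE)
  lnum <- as.numeric(factor(cell$load, levels = loads))
  betas <- purrr::map_dfr(subjects, function(s) {
    rows <- cell$subject == s
    y <- cell$value[rows]
    x <- lnum[rows]
    b <- if (sd(y) == 0) 0 else unname(coef(lm(y ~ x))[2])
    tibble::tibble(subject = s, beta = b, constant = sd(y) == 0)
  })
  if (sd(betas$beta) == 0) {
    # degenerate (noise-free) case: identical betas across subjects
    tt <- list(
      statistic = if (mean(betas$beta) == 0) 0 else Inf * sign(mean(betas$beta)),
      parameter = length(subjects) - 1,
      p.value = if (mean(betas$beta) == 0) 1 else 0
    )
  } else {
    tt <- t.test(betas$beta)
  }
  wide <- tidyr::pivot_wider(cell, names_from = "load", values_from = "value")
  pw <- purrr::map_dfr(seq_len(length(loads) - 1), function(i) {
    a <- wide[[as.character(loads[i])]]
    b <- wide[[as.character(loads[i + 1])]]
    p_val <- if (sd(b - a) == 0) {
      if (mean(b - a) == 0) 1 else 0
    } else {
      t.test(b, a, paired = TRUE)$p.value
    }
    tibble::tibble(
      contrast = paste(loads[i + 1], "-", loads[i]),
      estimate = mean(b - a), p_value = p_val
    )
  })
  pw$p_adjusted <- bh_fdr(pw$p_value)
  structure(
    list(
      betas = betas,
      mean_beta = mean(betas$beta),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      pairwise = pw, loads = loads
    ),
    class = "load_effect"
  )
}

#' @export
print.load_effect <- function(x, ...) {
  cat(sprintf(
    "<load_effect> mean beta %.4g, t(%d) = %.3f, p = %.3g\n",
    x$mean_beta, x$df, x$t, x$p
  ))
  invisible(x)
}

#' Glance at a load effect
#' @param x a `load_effect`
#' @param ... unused
#' @return one-row tibble
#' @export
glance.load_effect <- function(x, ...) {
  tibble::tibble(
    mean_beta = x$mean_beta, statistic = x$t, df = x$df, p_value = x$p,
    n_subjects = nrow(x$betas)
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin wrapper around `p.adjust(method = "BH")`, the standard step-up
#' procedure with monotonicity enforcement.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values (same length)
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Within-subject centering for repeated-measures display
#'
#' Subtracts each subject's cross-condition mean and adds back the global
#' grand mean, so between-subject offsets are removed while every condition
#' mean is preserved exactly. Used for display of within-person effects.
#'
#' @param data tibble with `subject`, `condition`, `value` (complete design)
#' @return the tibble with `value` replaced by its centered version
#' @export
within_subject_center <- function(data) {
  stopifnot(all(c("subject", "condition", "value") %in% names(data)))
  counts <- table(data$subject, data$condition)
  if (any(counts != 1)) stop("design must be complete (one value per cell)", call. = FALSE)
  grand <- mean(data$value)
  dplyr::mutate(
    dplyr::group_by(data, .data$subject),
    value = .data$value - mean(.data$value) + grand
  ) |> dplyr::ungroup()
}

#' Partial repeated-measures correlation
#'
#' Within-subject association between the load modulations of two measures
#' after removing subject and condition (load) main effects: the model
#' `x1 ~ 1 + ID + LOAD + x2` (ID and LOAD categorical) is compared with the
#' null `x1 ~ 1 + ID + LOAD` by a nested-model F-test. The reported
#' coefficient is `sign(beta_x2) * sqrt(partial eta squared)`.
#'
#' @param data tibble with `subject`, `load`, `x1`, `x2` (complete design)
#' @return list of class `rmcorr_result`: `r`, `p`, `df`, main-effect
#'   directions of both variables
#' @export
partial_rmcorr <- function(data) {
  stopifnot(all(c("subject", "load", "x1", "x2") %in% names(data)))
  subjects <- unique(data$subject)
  loads <- sort(unique(data$load))
  if (length(subjects) < 3 || length(loads) < 2) {
    stop("need >= 3 subjects and >= 2 conditions", call. = FALSE)
  }
  id <- factor(data$subject)
  ld <- factor(data$load, levels = loads)
  full <- lm(data$x1 ~ id + ld + data$x2)
  if (anyNA(coef(full))) {
    stop("`x2` is collinear with the subject/load design", call. = FALSE)
  }
  null <- lm(data$x1 ~ id + ld)
  an <- anova(null, full)
  rss0 <- an$RSS[1]
  rss1 <- an$RSS[2]
  eta_p <- (rss0 - rss1) / rss0
  b3 <- coef(full)[["data$x2"]]
  slope_dir <- function(y) {
    sign(unname(coef(lm(y ~ as.numeric(ld) + id))[2]))
  }
  structure(
    list(
      r = sign(b3) * sqrt(eta_p),
      p = an$`Pr(>F)`[2],
      statistic = an$F[2],
      df1 = an$Df[2], df2 = an$Res.Df[2],
      direction_x1 = slope_dir(data$x1),
      direction_x2 = slope_dir(data$x2)
    ),
    class = "rmcorr_result"
  )
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf(
    "<rmcorr> r = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
    x$r, x$df1, x$df2, x$statistic, x$p
  ))
  invisible(x)
}

#' Glance at a partial repeated-measures correlation
#' @param x an `rmcorr_result`
#' @param ... unused
#' @return one-row tibble
#' @export
glance.rmcorr_result <- function(x, ...) {
  tibble::tibble(
    r = x$r, statistic = x$statistic, df1 = x$df1, df2 = x$df2, p_value = x$p,
    direction_x1 = x$direction_x1, direction_x2 = x$direction_x2
  )
}
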