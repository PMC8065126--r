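#' Extract per-subject, per-load features from a synthetic study
#'
#' The standard feature battery: aperiodic slope per channel
#' ([welch_psd()] + [fit_slope()]), phasic pupil scalar
#' ([phasic_derivative()] + [extract_phasic()]), and drift-diffusion
#' estimates per subject ([ddm_fit()], drift + non-decision-time variant).
#' Generation is streamed subject by subject so memory stays flat; with the
#' counter-based seed scheme the result is identical to extracting from a
#' monolithic [gen_study()] call.
#'
#' @param config a [study_config()]
#' @param spec an [effect_spec()]
#' @param what subset of `c("slope", "pupil", "ddm")`
#' @param subjects subject indices (default all)
#' @param ddm_variant model variant passed to [ddm_fit()]
#' @param ddm_dt Euler step for behavior generation
#' @return list of tibbles: `slopes` (subject, load, channel, slope),
#'   `pupil` (subject, load, pupil_phasic), `ddm` (subject, load, v, t0, a),
#'   `truth`
#' @export
extract_study_features <- function(config, spec = effect_spec(),
                                   what = c("slope", "pupil", "ddm"),
                                   subjects = seq_len(config$n_subjects),
                                   ddm_variant = "drift_ndt",
                                   ddm_dt = 1e-3) {
  slopes <- list()
  pupil <- list()
  ddm <- list()
  truth <- NULL
  for (s in subjects) {
    comp <- c(
      if ("slope" %in% what) "signals",
      if ("pupil" %in% what) "pupil",
      if ("ddm" %in% what) "behavior"
    )
    st <- gen_study(config, spec, subjects = s, components = comp, ddm_dt = ddm_dt)
    truth <- dplyr::bind_rows(truth, st$truth)
    for (l in seq_len(config$n_loads)) {
      if ("slope" %in% what) {
        psd <- welch_psd(st$signals[[1]][[l]], span = c(0.5, 3))
        sl <- fit_slope(psd)
        sl$subject <- s
        sl$load <- l
        slopes[[length(slopes) + 1]] <- sl
      }
      if ("pupil" %in% what) {
        ph <- extract_phasic(phasic_derivative(clean_pupil(st$pupil[[1]][[l]])))
        pupil[[length(pupil) + 1]] <- tibble::tibble(
          subject = s, load = l, pupil_phasic = as.numeric(ph)
        )
      }
    }
    if ("ddm" %in% what) {
      fit <- ddm_fit(st$behavior, variant = ddm_variant, seed = child_seed(config$seed, 17, s))
      est <- fit$params
      ddm[[length(ddm) + 1]] <- tibble::tibble(
        subject = s, load = seq_len(config$n_loads),
        v = per_load(est$v, config$n_loads),
        a = per_load(est$a, config$n_loads),
        t0 = per_load(est$t0, config$n_loads)
      )
    }
  }
  list(
    slopes = if (length(slopes)) dplyr::bind_rows(slopes) else NULL,
    pupil = if (length(pupil)) dplyr::bind_rows(pupil) else NULL,
    ddm = if (length(ddm)) dplyr::bind_rows(ddm) else NULL,
    truth = truth
  )
}

#' Per-subject load slope of a feature table
#'
#' Convenience wrapper: for each subject (and optional grouping column) fit
#' `value ~ load` (numeric 1..K) and return the slope.
#'
#' @param data tibble with `subject`, `load`, `value` and optionally `by`
#' @param by optional extra grouping column name (e.g. `"channel"`)
#' @return tibble: `subject` (, `by`), `slope`
#' @export
load_slopes <- function(data, by = NULL) {
  grp <- c("subject", by)
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(grp))),
    slope = {
      x <- as.numeric(.data$load)
      if (sd(.data$value) == 0) 0 else unname(coef(lm(.data$value ~ x))[2])
    },
    .groups = "drop"
  )
}

#' Assemble a subject x condition x feature cube from a long table
#'
#' @param data tibble with `subject`, `load`, feature id column and `value`
#' @param feature name of the feature id column
#' @return 3-d array with dimnames, suitable for [task_pls()] and
#'   [cluster_perm_test()] front-ends
#' @export
as_data_cube <- function(data, feature = "channel") {
  subjects <- sort(unique(data$subject))
  loads <- sort(unique(data$load))
  feats <- unique(data[[feature]])
  cube <- array(
    NA_real_, c(length(subjects), length(loads), length(feats)),
    dimnames = list(subjects, loads, feats)
  )
  for (i in seq_len(nrow(data))) {
    cube[
      as.character(data$subject[i]), as.character(data$load[i]),
      as.character(data[[feature]][i])
    ] <- data$value[i]
  }
  if (anyNA(cube)) stop("incomplete design: missing subject x load x feature cells", call. = FALSE)
  cube
}
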