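#' Pipeline configuration
#'
#' Bundles the study configuration, planted effects and per-stage options
#' into one validated object with a content hash recorded in all outputs.
#'
#' @param config a [study_config()]
#' @param spec an [effect_spec()]
#' @param stages subset of `c("synth", "features", "stats")`
#' @param out_dir output directory or `NULL` for no file output
#' @param n_perm permutations for the statistical stage
#' @param n_boot bootstrap resamples for PLS
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(config, spec = effect_spec(),
                            stages = c("synth", "features", "stats"),
                            out_dir = NULL, n_perm = 500, n_boot = 500) {
  pc <- structure(
    list(
      config = config, spec = spec, stages = stages,
      out_dir = out_dir, n_perm = n_perm, n_boot = n_boot
    ),
    class = "pipeline_config"
  )
  pc$hash <- rlang::hash(pc[c("config", "spec", "stages", "n_perm", "n_boot")])
  pc
}

#' Validate a pipeline configuration
#'
#' Cross-stage consistency diagnostics: band limits against Nyquist,
#' analysis windows against the epoch, minimum counts. Returns a character
#' vector of issues (empty when the configuration is sound); never throws.
#'
#' @param pc a [pipeline_config()]
#' @return character vector of named violations
#' @export
validate_config <- function(pc) {
  issues <- character()
  cfg <- pc$config
  spec <- pc$spec
  nyq <- cfg$fs / 2
  if (max(spec$gamma_band) * 1.2 >= nyq) {
    issues <- c(issues, sprintf(
      "gamma band upper edge %g Hz (x1.2 bandwidth) reaches Nyquist %g Hz",
      max(spec$gamma_band), nyq
    ))
  }
  if (cfg$epoch[1] > -0.5) {
    issues <- c(issues, "epoch leaves less than 0.5 s of pre-stimulus baseline")
  }
  if (cfg$epoch[2] < cfg$stimulus[2]) {
    issues <- c(issues, "epoch ends before stimulus offset")
  }
  ent_win <- 0.5
  if (cfg$epoch[2] - cfg$epoch[1] < ent_win) {
    issues <- c(issues, "entropy window longer than the epoch")
  }
  if (cfg$n_subjects < 3 && "stats" %in% pc$stages) {
    issues <- c(issues, "statistics stage needs at least 3 subjects")
  }
  if (any(per_load(spec$alpha_abundance, cfg$n_loads) < 0 |
    per_load(spec$alpha_abundance, cfg$n_loads) > 1)) {
    issues <- c(issues, "alpha abundance outside [0, 1]")
  }
  issues
}

#' Run the generate-extract-test pipeline
#'
#' Executes the requested stages in order: synthesize ground truth (and
#' behavior), extract features (aperiodic slope per channel, phasic pupil,
#' diffusion fits), and run the group statistics (load betas per measure
#' and a behavioral PLS linking channel-wise slope modulation to drift and
#' pupil modulation). Results, a manifest (seed, configuration hash) and
#' tidy CSV tables are written to `out_dir` when set.
#'
#' @param pc a [pipeline_config()]
#' @return list of class `pipeline_result` with `features`, `stats`,
#'   `manifest`
#' @export
run_pipeline <- function(pc) {
  issues <- validate_config(pc)
  if (length(issues)) {
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "), call. = FALSE)
  }
  res <- list(manifest = list(
    hash = pc$hash, seed = pc$config$seed,
    stages = pc$stages, timestamp = NA_character_
  ))
  stage <- "synth"
  tryCatch(
    {
      if ("synth" %in% pc$stages) {
        res$truth <- gen_truth(pc$config, pc$spec)
      }
      if ("features" %in% pc$stages) {
        stage <- "features"
        res$features <- extract_study_features(pc$config, pc$spec)
      }
      if ("stats" %in% pc$stages) {
        stage <- "stats"
        f <- res$features
        slope_lb <- load_betas(dplyr::rename(
          dplyr::filter(f$slopes, .data$channel %in% pc$config$posterior),
          value = "slope"
        ))
        pupil_lb <- load_betas(dplyr::rename(f$pupil, value = "pupil_phasic"))
        drift_lb <- load_betas(dplyr::rename(f$ddm, value = "v"))
        brain <- load_slopes(dplyr::rename(f$slopes, value = "slope"), by = "channel")
        brain_m <- tidyr::pivot_wider(brain, names_from = "channel", values_from = "slope")
        behavior <- dplyr::inner_join(
          load_slopes(dplyr::rename(f$ddm, value = "v")),
          load_slopes(dplyr::rename(f$pupil, value = "pupil_phasic")),
          by = "subject", suffix = c("_drift", "_pupil")
        )
        stopifnot(all(brain_m$subject == behavior$subject))
        bpls <- behavioral_pls(
          as.matrix(brain_m[, -1]),
          as.matrix(behavior[, -1]),
          n_perm = pc$n_perm, n_boot = pc$n_boot,
          seed = child_seed(pc$config$seed, 23)
        )
        res$stats <- list(
          slope_load = slope_lb, pupil_load = pupil_lb, drift_load = drift_lb,
          behavioral_pls = bpls
        )
      }
    },
    error = function(e) {
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.null(pc$out_dir)) {
    dir.create(pc$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res$manifest, file.path(pc$out_dir, "manifest.json"),
      auto_unbox = TRUE
    )
    if (!is.null(res$truth)) {
      utils::write.csv(res$truth, file.path(pc$out_dir, "truth.csv"), row.names = FALSE)
    }
    if (!is.null(res$features$slopes)) {
      utils::write.csv(res$features$slopes, file.path(pc$out_dir, "slopes.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(res$features$pupil)) {
      utils::write.csv(res$features$pupil, file.path(pc$out_dir, "pupil.csv"),
        row.names = FALSE
      )
    }
  }
  class(res) <- "pipeline_result"
  res
}
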