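#' Configuration of a synthetic uncertainty study
#'
#' Defaults mirror the emulated experiment: 4 load conditions, 64 trials per
#' load, 500 Hz sampling, 3 s stimulus epochs embedded in a -1 to 4.25 s
#' window, 16 channels on a labelled 4 x 4 grid (8-connected neighbor map)
#' whose lower half plays the role of posterior cortex.
#'
#' @param n_subjects number of subjects
#' @param n_loads number of load conditions (default 4)
#' @param trials_per_load trials per condition (default 64)
#' @param fs sampling rate, Hz (default 500)
#' @param epoch length-2 epoch span in seconds relative to stimulus onset
#' @param stimulus length-2 stimulus window, seconds
#' @param grid channel grid as `c(nrow, ncol)` (default `c(4, 4)`)
#' @param seed global integer seed; all child seeds derive from it
#' @return list of class `study_config`
#' @export
study_config <- function(n_subjects, n_loads = 4, trials_per_load = 64,
                         fs = 500, epoch = c(-1, 4.25), stimulus = c(0, 3),
                         grid = c(4, 4), seed = 1) {
  stopifnot(
    n_subjects >= 1, n_loads >= 1, trials_per_load >= 1, fs > 0,
    epoch[1] <= stimulus[1], epoch[2] >= stimulus[2]
  )
  n_channels <- prod(grid)
  labs <- sprintf("ch%02d", seq_len(n_channels))
  rows <- rep(seq_len(grid[1]), times = grid[2])
  structure(
    list(
      n_subjects = n_subjects, n_loads = n_loads,
      trials_per_load = trials_per_load, fs = fs,
      epoch = epoch, stimulus = stimulus,
      grid = grid, n_channels = n_channels, channels = labs,
      channel_rows = rows,
      posterior = labs[rows > grid[1] / 2],
      neighbors = grid_neighbors(grid[1], grid[2]),
      seed = seed
    ),
    class = "study_config"
  )
}

#' Planted effects and couplings of a synthetic study
#'
#' Per-load generating values for every ground-truth field, the
#' between-subject SDs around them, and the loading of the latent subject
#' factor `g` on the within-subject load slopes of drift rate, aperiodic
#' exponent, alpha abundance and pupil gain (the planted "triad" coupling).
#' Defaults plant the canonical directions: with rising load, drift rate
#' falls, non-decision time rises, the aperiodic exponent falls (spectrum
#' flattens), alpha abundance falls, and the phasic pupil response grows.
#'
#' @param chi per-load aperiodic exponents
#' @param alpha_abundance per-load expected alpha-burst abundance
#' @param alpha_snr alpha burst power SNR (scalar or per load)
#' @param gamma_gain amplitude of the coupled gamma component
#' @param kappa phase-amplitude coupling depth in `[0, 1]`
#' @param gamma_band Hz band of the coupled gamma component
#' @param ssvep_amp 30 Hz entrained-response amplitude
#' @param v,a,t0 diffusion parameters (per load where vectors)
#' @param pupil_gain per-load phasic pupil gain
#' @param subject_sd named list of between-subject SDs
#' @param coupling latent-factor loading on the load slopes (0 = no triad)
#' @return list of class `effect_spec`
#' @export
effect_spec <- function(chi = c(1.3, 1.2, 1.1, 1.0),
                        alpha_abundance = c(0.5, 0.4, 0.3, 0.2),
                        alpha_snr = 10,
                        gamma_gain = 0.5,
                        kappa = 0.6,
                        gamma_band = c(80, 150),
                        ssvep_amp = 0.75,
                        v = c(2.0, 1.6, 1.2, 0.8),
                        a = 1.5,
                        t0 = c(0.30, 0.33, 0.37, 0.40),
                        pupil_gain = c(0.5, 1.0, 1.5, 2.0),
                        subject_sd = list(
                          chi = 0.08, alpha_abundance = 0.04, v = 0.15,
                          t0 = 0.02, pupil_gain = 0.15
                        ),
                        coupling = 0.5) {
  stopifnot(kappa >= 0, kappa <= 1, all(a > 0), all(t0 >= 0))
  structure(
    list(
      chi = chi, alpha_abundance = alpha_abundance, alpha_snr = alpha_snr,
      gamma_gain = gamma_gain, kappa = kappa, gamma_band = gamma_band,
      ssvep_amp = ssvep_amp, v = v, a = a, t0 = t0,
      pupil_gain = pupil_gain, subject_sd = subject_sd, coupling = coupling
    ),
    class = "effect_spec"
  )
}

per_load <- function(x, n_loads) {
  if (length(x) == 1) rep(x, n_loads) else x
}

#' Ground-truth generating parameters for each subject
#'
#' Draws the latent factor `g` and the per-subject, per-load parameter
#' table. Fields participating in the triad (`v`, `chi`, `alpha_abundance`,
#' `pupil_gain`) have their within-subject load slopes scaled by
#' `1 + coupling * g`; all fields receive a subject-constant offset drawn
#' from the configured between-subject SDs. Values with hard ranges are
#' clamped (abundance to `[0, 1]`, `t0` to `>= 0`).
#'
#' @param config a [study_config()]
#' @param spec an [effect_spec()]
#' @return tibble: `subject`, `g`, `load`, one column per parameter
#' @export
gen_truth <- function(config, spec) {
  n_l <- config$n_loads
  for (f in c("chi", "alpha_abundance", "v", "a", "t0", "pupil_gain",
              "alpha_snr")) {
    if (!length(spec[[f]]) %in% c(1, n_l)) {
      stop("effect_spec field `", f, "` must have length 1 or n_loads", call. = FALSE)
    }
  }
  coupled <- c("v", "chi", "alpha_abundance", "pupil_gain")
  plain <- c("a", "t0", "alpha_snr")
  purrr::map_dfr(seq_len(config$n_subjects), function(s) {
    with_seed(child_seed(config$seed, 101, s), {
      g <- rnorm(1)
      row <- tibble::tibble(
        subject = s, g = g, load = seq_len(n_l)
      )
      for (f in coupled) {
        base <- per_load(spec[[f]], n_l)
        ctr <- mean(base)
        slope_scale <- 1 + spec$coupling * g
        offs <- rnorm(1, 0, spec$subject_sd[[f]] %||% 0)
        row[[f]] <- ctr + (base - ctr) * slope_scale + offs
      }
      for (f in plain) {
        base <- per_load(spec[[f]], n_l)
        offs <- rnorm(1, 0, spec$subject_sd[[f]] %||% 0)
        row[[f]] <- base + offs
      }
      row$alpha_abundance <- pmin(1, pmax(0, row$alpha_abundance))
      row$chi <- pmax(0, row$chi)
      row$t0 <- pmax(0.05, row$t0)
      row$a <- pmax(0.3, row$a)
      row$kappa <- spec$kappa
      row$gamma_gain <- spec$gamma_gain
      row$ssvep_amp <- spec$ssvep_amp
      row
    })
  })
}

# one trial's multichannel signal matrix (channel x time)
gen_trial_signals <- function(config, spec, truth_row, seed) {
  fs <- config$fs
  dur <- config$epoch[2] - config$epoch[1]
  n <- round(dur * fs)
  tt <- config$epoch[1] + (seq_len(n) - 1) / fs
  stim <- tt >= config$stimulus[1] & tt <= config$stimulus[2]
  stim_dur <- config$stimulus[2] - config$stimulus[1]
  out <- matrix(0, config$n_channels, n)
  post <- config$channels %in% config$posterior
  for (ch in seq_len(config$n_channels)) {
    x <- gen_aperiodic(truth_row$chi, dur, fs, seed = child_seed(seed, ch, 1))
    if (post[ch]) {
      # alpha bursts restricted to the stimulus window; abundances too small
      # to fit one three-cycle burst degrade gracefully to "no bursts"
      ab <- truth_row$alpha_abundance
      if (ab * stim_dur < 3 / 10) ab <- 0
      b <- gen_bursts(10, ab, truth_row$alpha_snr,
        stim_dur, fs,
        seed = child_seed(seed, ch, 2)
      )
      burst_sig <- numeric(n)
      stim_idx <- which(stim)
      nb <- min(length(b$signal), length(stim_idx))
      burst_sig[stim_idx[seq_len(nb)]] <- b$signal[seq_len(nb)]
      # alpha phase inside bursts (sin burst = cos(phase), phase = wt - pi/2)
      phase <- rep(NA_real_, n)
      st_t <- tt[stim_idx] - config$stimulus[1]
      for (bi in seq_len(nrow(b$intervals))) {
        inb_idx <- stim_idx[st_t >= b$intervals$onset[bi] & st_t <= b$intervals$offset[bi]]
        phase[inb_idx] <- 2 * pi * 10 * (tt[inb_idx] - config$stimulus[1] - b$intervals$onset[bi]) - pi / 2
      }
      # gamma noise whose envelope follows the alpha phase inside bursts
      gnoise <- with_seed(child_seed(seed, ch, 3), rnorm(n))
      gam <- fft_bandpass(gnoise, fs, spec$gamma_band[1], spec$gamma_band[2])
      gam <- gam / sd(gam)
      env <- rep(0.5, n)
      inb <- !is.na(phase)
      env[inb] <- (1 + truth_row$kappa * cos(phase[inb])) / 2
      ssvep <- numeric(n)
      ssvep[stim] <- truth_row$ssvep_amp * sin(2 * pi * 30 * (tt[stim] - config$stimulus[1]))
      out[ch, ] <- x + burst_sig + truth_row$gamma_gain * gam * env + ssvep
    } else {
      out[ch, ] <- x
    }
  }
  out
}

#' Generate a synthetic study (signals + behavior + pupil + ground truth)
#'
#' Composes the component generators into a fully indexed study. Every
#' random draw uses a child seed derived from `(config$seed, subject, load,
#' trial, channel)`, so any subject subset regenerates bit-identically.
#' Posterior channels carry alpha bursts, phase-coupled gamma and the 30 Hz
#' entrained response on top of the scale-free background; other channels
#' carry background only, giving spatial tests a planted target.
#'
#' @param config a [study_config()]
#' @param spec an [effect_spec()]
#' @param subjects subset of subject indices to realize (default all)
#' @param components which data blocks to generate
#' @param ddm_dt Euler step for behavior simulation, seconds
#' @return list of class `synthetic_study`: `config`, `spec`, `truth`,
#'   `signals[[subject]][[load]]` ([trial_set()]), `behavior` (tibble),
#'   `pupil[[subject]][[load]]` ([pupil_set()])
#' @export
gen_study <- function(config, spec = effect_spec(),
                      subjects = seq_len(config$n_subjects),
                      components = c("signals", "behavior", "pupil"),
                      ddm_dt = 1e-3) {
  stopifnot(inherits(config, "study_config"), inherits(spec, "effect_spec"))
  truth <- gen_truth(config, spec)
  truth <- truth[truth$subject %in% subjects, , drop = FALSE]
  dur <- config$epoch[2] - config$epoch[1]
  signals <- list()
  pupil <- list()
  behavior <- list()
  for (s in subjects) {
    sig_s <- list()
    pup_s <- list()
    for (l in seq_len(config$n_loads)) {
      tr_row <- truth[truth$subject == s & truth$load == l, ]
      if ("signals" %in% components) {
        arr <- array(NA_real_, c(
          config$trials_per_load, config$n_channels,
          round(dur * config$fs)
        ))
        for (tr in seq_len(config$trials_per_load)) {
          arr[tr, , ] <- gen_trial_signals(
            config, spec, tr_row,
            seed = child_seed(config$seed, 7, s, l, tr)
          )
        }
        sig_s[[l]] <- trial_set(arr, config$fs,
          t0 = config$epoch[1],
          channels = config$channels
        )
      }
      if ("behavior" %in% components) {
        beh <- ddm_simulate(
          ddm_params(v = tr_row$v, a = tr_row$a, t0 = tr_row$t0),
          n_trials = config$trials_per_load,
          seed = child_seed(config$seed, 11, s, l),
          dt = ddm_dt
        )
        beh$subject <- as.integer(s)
        beh$load <- as.integer(l)
        behavior[[length(behavior) + 1]] <- beh
      }
      if ("pupil" %in% components) {
        tracelist <- lapply(seq_len(config$trials_per_load), function(tr) {
          gen_pupil_trace(tr_row$pupil_gain, dur, config$fs,
            seed = child_seed(config$seed, 13, s, l, tr),
            t0 = config$epoch[1]
          )
        })
        pup_s[[l]] <- pupil_set(do.call(rbind, tracelist), config$fs,
          t0 = config$epoch[1]
        )
      }
    }
    signals[[as.character(s)]] <- sig_s
    pupil[[as.character(s)]] <- pup_s
  }
  structure(
    list(
      config = config, spec = spec, truth = truth,
      signals = if ("signals" %in% components) signals else NULL,
      behavior = if (length(behavior)) {
        dplyr::select(
          dplyr::bind_rows(behavior),
          "subject", "load", "trial", "rt_s", "accuracy"
        )
      } else {
        NULL
      },
      pupil = if ("pupil" %in% components) pupil else NULL
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d subject(s) x %d loads x %d trials, %d channels @ %g Hz\n",
    length(unique(x$truth$subject)), x$config$n_loads,
    x$config$trials_per_load, x$config$n_channels, x$config$fs
  ))
  invisible(x)
}

#' Write a synthetic study to a plain-text bundle
#'
#' Writes `behavior.csv`, `truth.csv`, `config.yaml` and, when signals are
#' present, one `signals_s<subject>_l<load>.csv` per cell (long format) into
#' `path`.
#'
#' @param study a `synthetic_study`
#' @param path output directory (created if missing)
#' @param signals also write the (large) signal tables
#' @return `path`, invisibly
#' @export
write_study <- function(study, path, signals = FALSE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(study$behavior)) {
    utils::write.csv(study$behavior, file.path(path, "behavior.csv"), row.names = FALSE)
  }
  utils::write.csv(study$truth, file.path(path, "truth.csv"), row.names = FALSE)
  cfg <- study$config
  cfg$neighbors <- NULL
  yaml::write_yaml(cfg, file.path(path, "config.yaml"))
  if (signals && !is.null(study$signals)) {
    for (s in names(study$signals)) {
      for (l in seq_along(study$signals[[s]])) {
        utils::write.csv(
          tidy(study$signals[[s]][[l]]),
          file.path(path, sprintf("signals_s%s_l%d.csv", s, l)),
          row.names = FALSE
        )
      }
    }
  }
  invisible(path)
}
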