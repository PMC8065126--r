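# oscidyn

Tools for asking how task uncertainty modulates cortical excitability in
multichannel electrophysiology — and for checking, end to end, that every
stage of such an analysis actually recovers what it claims to measure.

When observers must monitor more potential target features ("load", coded
1–4), cortical dynamics shift in a characteristic way: the aperiodic (1/f)
spectral background flattens, broadband sample entropy rises, narrowband
alpha rhythms become scarcer, phasic pupil responses grow, and evidence
accumulation slows. `oscidyn` implements the measures behind each of those
statements, the drift-diffusion model that summarizes the behavior, and the
group statistics that link them across subjects — plus a synthetic-study
generator with known ground truth, so the whole chain is testable without
any recordings.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic studies with planted effects | `study_config()`, `effect_spec()`, `gen_study()`, `gen_aperiodic()`, `gen_bursts()`, `gen_pac()`, `gen_pupil_trace()` |
| Spectral measures | `welch_psd()` + `fit_slope()` (aperiodic slope, 7–13 Hz excluded), `morlet_tfr()`, `multitaper_gamma()` + `gamma_normalize()`, `ssvep_estimate()` |
| Irregularity | `bandstop_alpha()`, `sample_entropy()`, `time_resolved_entropy()` (time-resolved, across discontinuous trial segments, SampEn with m = 2, r = 0.5) |
| Rhythmic episodes | `fit_background()`, `detect_episodes()` (95th-percentile power + 3-cycle duration thresholds), `summarize_band_episodes()` |
| Phase–amplitude coupling | `pac_mi()` (16-bin normalized-entropy MI), `surrogate_mi()`, `pac_pipeline()`, `trough_locked_average()` |
| Decision model | `ddm_simulate()`, `ddm_loglik()`, `ddm_fit()`, `ddm_model_compare()`, `signature_slope()` |
| Pupil | `clean_pupil()`, `phasic_derivative()`, `extract_phasic()` |
| Group statistics | `load_betas()`, `bh_fdr()`, `within_subject_center()`, `partial_rmcorr()`, `cluster_perm_test()`, `task_pls()`, `behavioral_pls()` |
| Orchestration | `extract_study_features()`, `pipeline_config()`, `validate_config()`, `run_pipeline()` |

The core statistics in brief: sample entropy
SampEn(m, r, N) = −ln(A/B), the conditional probability that templates
matching for m points still match at m + 1 within r pooled SDs; the
aperiodic exponent as the OLS slope of log10 power on log10 frequency with
the alpha band excluded; the modulation index
MI = (ln N_bins − H)/ln N_bins of the phase-binned amplitude distribution,
surrogate-normalized; the two-boundary diffusion with drift v, boundary
separation a and non-decision time t0 fitted by maximum likelihood from the
first-passage-time series expansion; and task/behavioral PLS,
SVD of the condition–feature covariance (or behavior–feature correlation)
matrix with permutation tests on singular values, subject-bootstrap ratios
for feature weights, and brain scores V′P.

## Worked example

Generate a small synthetic study with the default planted effects, extract
the per-subject feature battery, and test the planted load trends:

```r
library(oscidyn)

cfg <- study_config(n_subjects = 6, trials_per_load = 16,
                    grid = c(2, 2), seed = 33)
res <- run_pipeline(pipeline_config(cfg, n_perm = 500, n_boot = 500))

res$stats$slope_load   # aperiodic slope flattens with load
res$stats$drift_load   # drift rate falls with load
res$stats$pupil_load   # phasic pupil response grows with load
glance(res$stats$behavioral_pls)
```

Output from this exact call:

```
<load_effect> mean beta 0.1294, t(5) = 8.415, p = 0.000389
<load_effect> mean beta -0.4326, t(5) = -7.509, p = 0.000662
<load_effect> mean beta 0.2045, t(5) = 8.144, p = 0.000453
# A tibble: 2 x 4
     lv singular_value crossblock_pct  p_perm
  <int>          <dbl>          <dbl>   <dbl>
1     1          2.17           97.7  0.00998
2     2          0.330           2.27 0.379
```

Reading it: per subject, each measure is regressed on load (1–4); the group
t-tests show the planted directions — the fitted 1/f slope becomes less
negative by ~0.13 per load step (flattening background, the excitability
proxy), drift falls by ~0.43 evidence units/s per step, and the phasic
pupil derivative rises. The behavioral PLS links channel-wise slope
modulation to drift and pupil modulation across subjects: one latent
variable carries ~98% of the crossblock covariance and is significant by
permutation (p ≈ 0.01) — the planted subject-level coupling ("triad")
recovered from raw synthetic signals.

## Vignette

`vignettes/oscidyn-methods.Rmd` documents the models and their assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, the numerical choices (edge handling,
tolerances, calibrated constants), and known limitations.
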