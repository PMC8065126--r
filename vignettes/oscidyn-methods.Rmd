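---
title: "Methods: rhythmic/aperiodic dynamics, decision modeling, and the statistics that link them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythmic/aperiodic dynamics, decision modeling, and the statistics that link them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and shape

`oscidyn` implements an analysis pipeline for studying how task uncertainty
(the number of cued target features, "load", coded 1-4) modulates cortical
excitability in multichannel electrophysiology, together with a
synthetic-study generator that plants every effect the pipeline is supposed
to find. The package is tidyverse-flavored where the data are naturally
tabular — feature tables, fit summaries and statistics are tibbles that
pipe, with `tidy()`/`glance()`/`autoplot()` methods — while epoched signals
and time-frequency arrays live in light array-backed containers
(`trial_set`, `tfr`), because `trial x channel x frequency x time` data are
not usefully long-format until summarized.

# Signal measures

## Aperiodic (1/f) slope

Power spectra are estimated from Hann-tapered trial epochs (the final 2.5 s
of stimulus presentation by default), zero-padded to 10 s, averaged over
trials, log10-transformed, and sampled at 41 log-spaced frequencies in
2-64 Hz. The aperiodic slope is the OLS coefficient of log10 power on log10
frequency after excluding 7-13 Hz, so a narrowband alpha peak cannot bias
the background estimate; flatter (less negative) slopes are conventionally
read as a higher excitation/inhibition ratio. The estimator is exactly
scale-invariant (rescaling the signal moves only the intercept). The unit
tests demonstrate, by construction, why the exclusion band matters: a peak
planted at 20 Hz — outside the band — biases the fit, the same peak at
10 Hz does not.

## Time-resolved sample entropy

Sample entropy is `-ln(A/B)` where `B` counts template pairs of length
`m = 2` within tolerance `r = 0.5` pooled SDs (Chebyshev distance) and `A`
the pairs still matching at length `m + 1`. The estimator runs across
discontinuous segments: for each 500 ms window (150 ms steps) the window's
samples from every trial are pooled; templates never span a segment
boundary, but pairs may, which is what makes short windows estimable. `r`
is referenced to the SD pooled over all segments in the window (rather than
per-segment), keeping the statistic comparable across windows and making it
exactly invariant to positive rescaling — hence no temporal baseline is
needed. The 8-15 Hz alpha band is removed beforehand by a zero-phase
Butterworth band-stop (enforced through a provenance flag) so narrowband
rhythms do not masquerade as regularity. Windows with no template match
return `NA`, never 0. The compiled match counter is verified against an
O(N^2) brute-force oracle exactly, and against the closed-form iid-Gaussian
limit `-ln(2 * pnorm(r / sqrt(2)) - 1)`.

## Rhythmic episodes

Single-trial rhythm detection follows the extended-BOSC logic: a 5-cycle
wavelet transform on 49 log-spaced frequencies (1-64 Hz); a linear aperiodic
background fit per channel that excludes 8-15 Hz and 28-32 Hz; a power
threshold at the 95th percentile of the exponential (chi-square, 2 df)
distribution implied by the fitted background mean; and a three-cycle
duration criterion. Supra-threshold points are grouped by time-frequency
adjacency and traced along their power ridge.

Two numerical choices deserve explanation. First, the wavelet smears power
in time (Gaussian envelope, `sigma_t = cycles / (2 pi f)`), so a
supra-threshold run extends beyond the true event. Each per-frequency run
is trimmed by the inverted step-edge crossing
`sigma_t * qnorm(1 - sqrt(threshold / peak))`, an SNR-adaptive correction,
scaled by a multiplier calibrated once at 0.85 against the generator (the
value that kept sample-level recall and precision of planted bursts above
0.8 simultaneously over a seed grid at burst SNR 10 and abundance 0.5;
margins at that operating point: recall ~0.83, precision ~0.81). Second,
the duration criterion is judged on the dominant-frequency run of each
group, because the union over neighboring frequency bins inflates duration
by extreme-value jitter. A residual limitation is intrinsic: a 5-cycle
wavelet cannot sharply separate 2-cycle from 3-cycle events, so at very
high SNR an isolated 2-cycle burst is still accepted in a minority of
background realizations.

Band summaries report abundance — the fraction of the analysis window
(stimulus period excluding its first 500 ms) covered by episodes whose mean
frequency falls in the band — with episode-free trials contributing zero.

## Phase-amplitude coupling

The modulation index is the normalized entropy deficit of the phase-binned
amplitude distribution: amplitudes are averaged in 16 uniform phase bins,
normalized to sum to one, and `MI = (ln 16 - H) / ln 16`, exactly 0 for
phase-independent amplitude and exactly 1 for single-bin concentration.
Empty bins contribute zero mass and are flagged. The episode-locked
pipeline band-passes the carrier (8-15 Hz, zero-phase FIR with order
`3 fs / f_low`), takes Hilbert phase, builds an amplitude bank from 40 to
150 Hz (2 Hz steps, +/-20% adaptive bandwidth), z-scores each narrowband
signal and squares the Hilbert magnitude, trims 250 ms filter edges, and
computes the MI over the 250 ms segments following episode onsets (or
preceding them, as a control). Significance is referenced to surrogates
that permute the segment pairing of phase and amplitude (identity
permutation excluded); the mean surrogate MI is subtracted. This
normalization is unbiased under independence but blind to coupling that
survives pairing shuffles — duplicated identical segments defeat it, a
blind spot the tests document deliberately. Trough-locked averages admit
troughs at local phase minima below `-pi + 2 pi f_high / fs + 0.01`; the
margin is sampling-aware because at 500 Hz the alpha phase advances ~0.13
rad per sample.

## Gamma power, SSVEP, decision signatures

High-frequency power uses five Slepian tapers on 400 ms windows stepped by
200 ms (45-90 Hz in 2.5 Hz steps, 8 Hz half-bandwidth smoothing — the
five-taper count follows `K = floor(2 T W - 1)`). Single-trial log10 power
is z-normalized against the -700 to -100 ms pre-stimulus baseline (trial
baseline subtracted, divided by the across-trial SD of baseline power, then
the condition-mean baseline removed, which zeroes the baseline window by
construction); the container refuses to normalize twice. The 30 Hz
entrained response is estimated from sliding 1 s Hann windows (100 ms
steps), condition-averaged, then normalized by subtracting the mean of the
28 and 32 Hz estimates (removing broadband/aperiodic contributions) and a
pre-stimulus temporal baseline — in that order, because reversing it
changes the variance. Ramping decision signatures (centro-parietal
positivity, lateralized mu-beta) are summarized by a windowed least-squares
slope (drift proxy) and a peri-response mean amplitude (threshold proxy)
after optional 8 Hz low-pass and condition-specific baseline.

# Decision model

Behavior is modeled as a two-boundary diffusion with unit diffusion
coefficient, symmetric start `a/2`, absorbing bounds at 0 and `a`, and
accuracy coding (upper bound = correct). RT = first-passage time + t0.
Premature responses at or below 250 ms are excluded; a fixed 5%
contamination mixes a uniform density over the observed RT range into the
likelihood. The first-passage density uses the adaptive small-time /
large-time series expansion truncated to relative error 1e-10; the tests
confirm it integrates to one over both bounds and matches the analytic
absorption probability and simulated RT histograms. Simulation is
blockwise Euler-Maruyama at a 0.1 ms step by default.

Fitting is per-subject maximum likelihood (`nlminb`, box constraints,
multi-start; standard errors from the observed information). The
non-decision-time upper bound is the 5th RT percentile per condition —
not the minimum, because contaminant RTs may legitimately undercut t0.
Model variants free drift, threshold and non-decision time per condition
("full"), subsets of them, or none ("null"); AIC/BIC replace the deviance
criterion used with hierarchical Bayesian estimation, which this package
deliberately does not implement (per-subject MLE is desk-scale and
testable; group-prior shrinkage is out of scope).

# Pupil

Cleaning masks vendor-flagged blinks plus samples where the z-standardized
first derivative of vertical gaze exceeds 3 SD, pads masks by 150 ms,
linearly interpolates (edge-constant), reports the interpolated fraction,
and excludes trials above 50% interpolation (the threshold is this
package's choice; the upstream description is silent). Cleaning is
idempotent. Phasic arousal is the first temporal derivative at 200 Hz —
traces are low-pass filtered below the target Nyquist with a zero-phase FFT
filter and resampled by interpolation — summarized as the median derivative
in the first 1.5 s after stimulus onset, trial-averaged per condition. The
derivative is exactly invariant to additive offsets. A 200 ms running
median is available for display only and never enters statistics.

# Group statistics

* **Load betas**: per-subject OLS slope of the outcome on numeric load
  (1..K), a two-sided one-sample t-test of the betas, and BH-FDR-adjusted
  paired t-tests between adjacent loads.
* **Partial repeated-measures correlation**: `x1 ~ ID + LOAD + x2` versus
  `x1 ~ ID + LOAD` (both factors categorical), F-test for the nested
  comparison, coefficient `sign(b3) * sqrt(partial eta^2)`, with the main
  effect directions of both variables reported for interpretability.
* **Within-subject centering** (display only): subtract subject means, add
  the grand mean; condition means are preserved exactly.
* **Cluster-based permutation**: pointwise one-sample t over subjects,
  two-sided entry threshold p < 0.05, spatio-temporal adjacency with a
  minimum of three neighboring channels per cluster, cluster mass = summed
  t, null distribution from sign-flipping subject effect maps (valid for
  symmetric paired designs and far cheaper than full re-randomization), and
  the conventional p < 0.025 per-sign significance reading. The matrix
  identity `t = m / sqrt((ss - S m^2)/((S-1)S))` lets all permutations share
  one matrix product, which is what makes 500-run calibration experiments
  affordable.
* **Task PLS**: SVD of the grand-mean condition x feature matrix after
  grand-mean column centering (the within-subject-centering alternative is
  a documented flag-level choice that was not adopted as default);
  permutation of condition labels within subject for LV significance;
  subject bootstrap with Procrustes alignment (to prevent sign/rotation
  drift) for bootstrap ratios BSR = V / SE, thresholded at |3| by
  convention. Brain scores are the exact projections `V'P`.
* **Behavioral PLS**: SVD of the behavior x feature correlation matrix;
  permutation shuffles behavior rows against the brain block; bootstrap as
  above, plus percentile CIs on the behavior-side correlation loadings.

# The synthetic-study generator

The generator's defaults are the study conditions the pipeline assumes:
4 load conditions x 64 trials, 500 Hz, 3 s stimulus epochs inside a
-1 to 4.25 s window, 16 channels on a 4 x 4 grid (8-connected neighbor
map) whose lower half plays posterior cortex. Per trial and channel the
signal sums: scale-free background via spectral synthesis (random phases,
amplitude `f^(-chi/2)`, unit variance) with a load-dependent exponent;
Hann-tapered 10 Hz bursts occupying a load-dependent fraction of the
stimulus window at SNR 10; band-limited 80-150 Hz noise whose envelope is
`(1 + kappa cos(phase)) / 2` against the alpha phase inside bursts
(kappa = 0.6); and a 30 Hz sinusoid during stimulation. Behavior comes
from the diffusion simulator with load-dependent drift (2.0 to 0.8) and
non-decision time (0.30 to 0.40 s) at fixed threshold 1.5; pupil traces
carry a gamma-shaped dilation transient whose gain rises with load. Each
element was chosen to be independently recoverable by exactly one pipeline
stage, which is what makes the recovery tests diagnostic.

Between-subject heterogeneity: every field receives a subject offset from
configurable normal distributions (defaults: chi 0.08, abundance 0.04,
drift 0.15, t0 0.02, pupil gain 0.15), and a standard-normal latent factor
`g` scales the within-subject load slopes of drift, exponent, abundance
and pupil gain by `1 + 0.5 g` — the planted "triad" coupling that the
behavioral PLS is meant to find. Abundances too small to fit one
three-cycle burst degrade to zero rather than erroring. One global seed
expands through a counter-based multiplicative hash (`child_seed()`) into
per-subject/load/trial/channel seeds, so any subset regenerates
bit-identically — feature extraction streams subject by subject in constant
memory and still matches a monolithic generation.

What the generator does not emulate — and therefore what green tests do
not certify about real recordings: volume conduction and sensor mixing,
ocular/muscle artifacts, non-stationary background beyond the planted load
effects, between-trial autocorrelation, realistic alpha waveform asymmetry,
and any fMRI signal. Statistical calibration results (FWE, p uniformity)
transfer only insofar as real effect maps satisfy the sign-flip symmetry
assumption.

# Problem sizes

Simulation scales used by the test suite and the acceptance script are the
package's documented desk-scale study conditions: 50-seed averages for
slope recovery (eight 2.5 s trials per seed); 100 null runs x 200
surrogates for PAC calibration and 20 seeds for PAC band recovery; 20 seeds
for episode recall/precision and abundance-trend recovery; 20 seeds x 256
trials/condition for diffusion recovery; 500 null simulations x 200
permutations for cluster FWE, 200 runs for PLS p uniformity, 500 runs for
the partial-rmcorr false-positive rate; and a 24-subject x 32-trial study
for the end-to-end triad recovery. The triad uses fewer trials per load
than the generator default because drift and pupil load-slopes are already
estimated with adequate precision there, while signal synthesis dominates
runtime.

# Known limitations

* Episode duration near the three-cycle criterion is soft (see above).
* Surrogate-based PAC normalization cannot detect coupling that is
  identical across all segments.
* The diffusion fit fixes the contamination weight at 5% rather than
  estimating it, matching the modeled design.
* The cluster test's sign-flip null assumes symmetric paired effects;
  skewed effect distributions would make it conservative or liberal.
* Per-subject MLE gives no shrinkage; with few trials per condition the
  drift estimates are noisy, which the triad analysis absorbs by using
  24 subjects.
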