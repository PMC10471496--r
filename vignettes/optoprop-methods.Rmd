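---
title: "Methods: from photostimulation to perception in optoprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from photostimulation to perception in optoprop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

optoprop analyses all-optical experiments in which groups of neurons in a
sensory area (S1) are photostimulated with single-cell precision while
two-photon calcium imaging records both S1 and a downstream area (S2), and the
animal reports perception of the stimulation by licking. This vignette
documents the models behind each stage, the parameters that matter, the
numerical choices that were genuinely open, and what the synthetic-data tests
do and do not establish about real recordings.

## The experiment the package models

A session interleaves three trial types in equal thirds, pseudorandomly with
no more than three consecutive trials of the same type: strong go trials (150
cells targeted, 760 ms of stimulation), variable go trials (5–50 cells in one
250 ms group, counts drawn from {5, 10, 20, 30, 40, 50}), and catch trials
(sham galvanometer movement, no laser). A pre-session block delivers ten
unconditional rewards at 10-s spacing to measure the reward-only neural
response. A lick in the 1-s response period scores a go trial as a hit and a
catch trial as a false positive; licks faster than 150 ms are implausibly
fast for perception and mark the trial "too soon" (excluded downstream).

## Preprocessing

Fluorescence is neuropil-corrected as `F = F_soma − 0.7 · F_neuropil` and
converted to ΔF/F against the whole-session mean of `F`. Two guards apply:

* **Denominator positivity.** Neuropil subtraction can drive a cell's session
  mean to or below zero, where ΔF/F is meaningless. Cells whose mean falls
  below `1e-6` times the 95th percentile of all session means are dropped and
  reported. The threshold is relative so that the guard is unit-free.
* **Transient plausibility.** Cells with max ΔF/F > 10 are discarded as
  unlikely to reflect spiking.

Trials are cut into −2 s … +8 s windows around onset. Frames while the
photostimulation laser is on — `ceiling(duration × rate)` frames — plus two
frames on each side are *blanked*: stored as `NA` and flagged in a mask, so no
downstream statistic can consume them silently. Window lengths are converted
to frames by rounding half-up; trials truncated by the recording edges are
dropped, not padded. Post-stimulus analyses subtract each trial's 2-s
pre-onset mean per cell; re-baselining a baselined tensor is an error rather
than a silent no-op.

## Behaviour

Detection sensitivity is `d' = z(hit rate) − z(false-alarm rate)`, with the
session-wide catch-trial false-alarm rate shared across stimulus strengths.
Rates of exactly 0 or 1 are corrected to `1/(2n)` and `1 − 1/(2n)`; the
correction convention is the standard log-linear one and is applied only at
the boundary. Sessions are kept when `d'(150) ≥ 0.95` and `d'(40∪50) ≥ 0.5`.
The psychometric curve is a least-squares logistic in the number of targeted
cells with its lower bound pinned at `d' = 0`; `x50` is the half-maximum
point. Pooled fits weight points, not sessions, equally (the weighting is not
otherwise determined; point-equal is the simplest defensible choice).

`psychometric_half_point()` computes the *expected* psychometric curve of a
behavioural generative model under a given design — including the same
extreme-rate clamping a finite session is subject to — and returns the fitted
half-point. This is deliberately the estimand of the fitting pipeline rather
than a property of the logistic alone: with saturating hit rates, `dmax` (and
therefore the half-point) depends on the rate correction, so an oracle that
ignored it would not be comparable to fitted values.

## Pre-stimulus population state and the SNR model

Population mean and variance are computed per trial from each cell's average
over the 0.5 s immediately preceding onset (15 frames at 30 Hz); the variance
uses the across-cell sample convention (n − 1). Because across-trial
population variance is close to log-normal, it is log-transformed by default;
`select_transform()` chooses between identity and log by comparing each
family's KL divergence from a 50-bin Laplace-smoothed histogram of the data.
Metrics are z-scored across *all* trials within a session before any split by
outcome, so hit/miss contrasts are on a common scale.

Trial outcome is modelled as logistic in the number of targeted cells and the
z-scored log population variance. McFadden's pseudo-R² (`1 − ll_model /
ll_null`) is reported for the full model and each single-regressor model; by
nesting, the full model's value bounds both. The hit-probability surface bins
trials by z-variance (bin width 0.5) crossed with the discrete target-count
categories; the SNR axis projects occupied bin centres, rescaled to the unit
square, onto the anti-diagonal (high count, low variance → high SNR) and
averages bin values per projection coordinate. Bin definitions are
conventions, fixed here and configurable, since nothing else pins them down.

## The synthetic-session generator

The generator's purpose is to produce sessions with the statistical structure
the analyses assume, with known ground truth:

* **Dynamics.** A discrete-time linear recurrent network at the frame
  interval, `r[t+1] = W r[t] + g·B f[t] + u[t] + ξ[t]`: spectral bound
  `R_true` of `W`, an AR(1) latent `f` (shared input, loadings drawn once,
  positive mean), photostimulation `u` injected as external input so that it
  propagates through `W`, and Gaussian private noise. Stability is guaranteed
  by `R_true < 1`; divergence is detected and aborts loudly.
* **Connectivity.** `W` is an iid Gaussian bulk plus, by default, a uniform
  rank-one mean-excitation mode at the bulk's spectral edge. The uniform mode
  matters for two reasons: a purely zero-mean random matrix has vanishing
  odd moments, so the *ensemble-mean* targeted-cell response after
  stimulation and the mean lag-1 autocorrelation are both ≈ 0 — no
  consistently decaying mean response exists to fit a timescale to — whereas
  real cortex has net positive recurrent excitation that loads stimulated
  activity onto a slow, population-wide mode. With `mean_coupling = 0` the
  pure random ensemble (used for calibrating the recurrence inversion) is
  recovered. Factor removal strips the uniform mode as shared structure, so
  the covariance-width estimator sees the same random bulk either way.
* **Calcium.** Poisson spikes with a softplus-rectified intensity, convolved
  with a peak-normalised difference-of-exponentials kernel (defaults: rise
  0.18 s, decay 1.4 s — GCaMP6s-like, configurable, not constants of the
  method), scaled into fluorescence with shot noise. The soma channel
  includes 0.7 × the neuropil channel so that the standard subtraction
  recovers the cell's own signal; the neuropil channel mixes the
  population-average signal (`neuropil_mix`, default 0.4).
* **Behaviour.** `P(hit) = logistic(β0 + βn·n + βv·v)` with `v` the
  within-session z-scored log population variance of the pre-stimulus rates,
  plus a fixed catch false-positive rate (0.1) and uniform 150–1000 ms lick
  latencies. Defaults (β0 = −1.68, βn = 0.12, βv = −0.5) were calibrated
  once, by `scripts/calibrate_outcome_model.R`, so the expected psychometric
  half-point of the standard design lands near 22 targeted cells; they are
  recorded as constructor defaults, not re-tuned.

What passing tests on this generator shows: the estimators recover known
ground truth through the full preprocessing chain under realistic noise,
shared variability and blanking. What it does not show: robustness to
non-linear dynamics, non-Poisson spiking, segmentation artefacts, slow drift,
or motion — none of which the generator emulates.

## Effective recurrence from the non-shared covariance width

The estimator follows three steps on concatenated 6.5-s pre-trial segments
(15 trials per draw, many draws, deterministic given a seed; blanked frames
never enter):

1. **Shared-activity removal.** Maximum-likelihood factor analysis (EM on the
   cells × cells covariance; cross-checked against `stats::factanal` in the
   tests) with the shared component reconstructed from posterior scores. The
   default removes **five** factors. One factor is not enough even when the
   latent input is one-dimensional: input entering recurrent *dynamics* is
   spread by the network over the span of `W^k B`, and with a single factor
   removed the leftover shared covariance inflates the width (and hence the
   inferred recurrence) drastically. Five factors also matches the
   variance-explained report the decomposition produces.
2. **Bias-corrected width.** The finite-sample covariance adds estimation
   noise to every off-diagonal entry. The default correction is split-half:
   covariance matrices from two disjoint temporal halves carry independent
   noise, so the across-pair covariance of their off-diagonals isolates the
   true squared width σ²_CC without a distributional model; it is floored at
   zero and flagged when negative. An analytic alternative — subtracting the
   expected noise variance `(c_ii c_jj + c_ij²)/(T−1)` — is provided and
   agrees on simulated data.
3. **Inversion.** For a linear recurrent network, `G(R) = N·(σ_CC/ā)²` is a
   monotone function of the spectral bound that collapses across network
   size. The package inverts a calibration table of `G` computed from *exact*
   stationary covariances (Lyapunov solutions via eigendecomposition of
   sampled weight matrices; N = 600, median over 16 weight seeds, anchors
   dense near R → 1; `scripts/calibrate_recurrence.R` regenerates it). Widths
   above the calibrated range clamp to the grid maximum (0.995) with a flag.
   Recorded subpopulations inherit the full network's covariance statistics,
   so data from a few hundred cells is inverted at the size of the local
   network — 50,000 by convention for cortical data.

Recovery is validated on rate-level simulations (N = 500, 30,000 frames,
R_true ∈ {0.5, 0.8, 0.95}, median over 10 seeds within ±0.05). Application to
ΔF/F is supported but quantitatively weaker: the indicator kernel adds
temporal correlation that inflates the width, which is acknowledged, not
corrected. On short calcium segments with `N_assumed = 50000` the inversion
typically saturates near the grid maximum; condition *contrasts* (hit versus
miss) remain meaningful because both conditions share the distortion.

## Network response timescale

For 250-ms-stimulation trials, targeted cells' ΔF/F is averaged up to 5.5 s
post-onset, corrected by each cell's mean over the 6.5-s pre-trial window;
10-trial subsample averages are fit with `A·exp(−t/τ)` by Levenberg–Marquardt
(three τ starts, best kept; fits with τ > 30 s or vanishing amplitude are
dropped and counted, and a session with > 50% failures is flagged). The
linear-network prediction is that the decay time along the leading eigenmode
scales as `1/(1−R)`; `relate_timescale_recurrence()` compares that
one-parameter law against an ordinary linear regression by r².

The estimator is validated on a simulated grid of R_true ∈ {0.8, 0.9, 0.95,
0.975}. The grid sits deliberately in the strongly recurrent regime: at
30 Hz with ≈ 0.33 s blanked, the map's decay time `−dt/ln R` is below 50 ms
for R = 0.5 — unmeasurable in principle — while at R = 0.99 (τ ≈ 3.3 s) the
5.5-s window cannot contain the decay. The validation simulations use a
dominant mean mode (`bulk_scale = 0.3`) and no shared input, because they
validate the timescale estimator in isolation; shared-input removal belongs
to, and is tested with, the covariance-width pipeline.

## Decoding

Per timeframe, an L2-penalised logistic regression (regularisation strength
0.001, the value a factor-10 sweep over 1e-7…1e3 selects; the sweep is
exposed as configuration) is trained on one scalar ΔF/F per cell under
stratified 4-fold cross-validation. Classes are balanced once per run by
subsampling the majority class; every retained trial is held out exactly once
per timepoint; blanked timepoints are skipped. Cross-condition evaluation
applies the stored per-fold models to trials of a third type (reward-only,
miss) that never enter training. Session-level significance uses a two-sided
Wilcoxon signed-rank test against chance (0.5, exact for small session
counts) with Bonferroni correction over tested timepoints. Classifier inputs
are baselined ΔF/F — the stationarity-motivated choice; raw ΔF/F would make
pre-stimulus offsets decodable.

## Excitation–inhibition balance

A cell is excited/inhibited on a trial set when a two-sided Wilcoxon
signed-rank test of its trial-wise mean baselined response (0–1.5 s,
unblanked frames) against zero is significant at 0.05, signed by the median;
fewer than five trials gives neutral with a flag. Window, level and test are
explicit configuration because the criterion is not otherwise pinned down.
Fractions versus stimulation strength are fit by weighted least squares with
inverse-variance weights clipped to their 25th–75th percentile range (with
equal weights this is exactly OLS). Correlations between excited and
inhibited fractions are compared across regions with Steiger's Z for
dependent, non-overlapping correlations (Pearson–Filon covariance, Fisher z);
a permutation oracle arbitrates its calibration in the tests. Cells within
15 µm of a beam centre (inclusive) are targets.

## Numerical conventions and degenerate inputs

* Frame indexing is 0-based in the trial table; times are ms from onset;
  missing licks/rewards are nulls (NaN-encoded in HDF5), never sentinels.
* Stimulation frames per trial: `ceiling(duration × rate)`; window lengths:
  round half-up.
* Variance: sample (n − 1) throughout; z-scores use the same convention.
* Degenerate inputs fail loudly and early: all-zero psychometric data
  (degenerate flag), constant covariates (flagged `NA`), zero-variance cells
  (excluded with a warning), single trials (z-scoring error), rank-deficient
  SNR designs (error), double baselining (error).
* Factor analysis accepts a near-flat likelihood as converged — weakly
  identified null-like data drifts slowly near the optimum — and otherwise
  restarts with jittered loadings before failing loudly.

## Problem sizes in the shipped tests

The suite exercises the estimators at the sizes their claims are made for:
recurrence recovery at 500 cells × 30,000 frames × 10 seeds per operating
point; the white-noise null at 50 cells × 50,000 frames; the timescale grid
at 200 cells × 120 trials per R; behavioural recovery at 400-trial sessions;
decoding calibration over 100 label permutations. Unit tests use smaller
fixtures generated in code.

## Known limitations

* The effective-recurrence inversion is calibrated for the iid-Gaussian
  linear-network ensemble; structured connectivity (clustered, low-rank,
  E/I-separated) will bend `G(R)` and is not covered.
* ΔF/F-level recurrence estimates saturate toward the inversion's grid
  maximum at realistic segment lengths; use condition contrasts, not
  absolute values, on calcium data.
* The timescale law is only measurable in the strongly recurrent regime at
  30 Hz; outside it the estimator honestly returns noise-floor values.
* The outcome model is conditionally independent across trials; no
  satiety, learning or slow motivational drift beyond what the latent
  variance induces.
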