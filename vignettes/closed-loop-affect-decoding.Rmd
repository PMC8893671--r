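---
title: "Simulating closed-loop decoded-affect neurofeedback experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop decoded-affect neurofeedback experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package emulates

`affectloop` simulates and analyses a closed-loop real-time fMRI (rtfMRI)
paradigm for testing whether self-induced affective brain states bias the
processing of subsequent stimuli. Subjects view affective pictures with
published normative valence and arousal ratings (1–9 Likert). A
multivoxel pattern decoder — a linear support vector machine over voxel
activity — is trained on passive-viewing (Id-PS) trials to decode valence
(and, separately, arousal) from each EPI volume (TR = 2 s). During
feedback-triggered (Mod-FS) trials the decoder's signed hyperplane
distance $h$ drives a visual feedback cue, and when the decoded state
satisfies a goal-state criterion ($h \ge 0.8$ for 4 consecutive volumes,
against a threshold that holds for 20 s and then decays linearly to zero
over 18 s), a congruent or incongruent test stimulus is triggered —
by default ("emergency") once the threshold reaches zero. Passive
modulation trials (Mod-PS) provide the randomly-triggered control
condition, cued-recall (Id-CR) trials measure unguided affect
regulation, and resting-state data furnish surrogate control trials.
The primary hypothesis is a general linear mixed-effects model (GLMM):
decoded valence of the test stimulus as a function of trial type,
controlling for normative valence, decoded arousal, demographics,
decoder accuracy, and the decoded valence of the immediately preceding
volume.

Because the original data are not deposited and the stimulus norms are
licence-restricted, everything here runs on synthetic data with planted
ground truth: the package's claims are about *method correctness*
(oracle equivalence, parameter recovery, calibration), never about
reproducing the original cohort's coefficients.

## The synthetic world

### Signal model

Each subject owns two unit-norm voxel patterns (valence, arousal). A
scan is
$$ X(t) = s_v(t)\,p_v + s_a(t)\,p_a + \text{drift}(t) + \varepsilon,$$
where $s_v$ is the double-gamma HRF (peak 6 s, undershoot 16 s, 6:1
ratio, unit peak) convolved with per-trial impulses of amplitude
$(v-5)/4$ — so Likert extremes map to $\pm 1$, keeping hyperplane
distances commensurate with the feedback range $[-1.25, 1.25]$ — and
analogously for arousal. Drift is a per-voxel linear slope
($N(0, 0.01)$ per volume, giving the online detrender something real to
remove); noise is independent Gaussian per voxel and volume.

Sustained activity (the 8-s recall window, and self-induction during
feedback) enters as per-TR levels convolved with the HRF kernel
normalized to unit *sum*, so a held level $L$ produces a steady-state
response of $L$; discrete stimuli use the unit-*peak* kernel so an
isolated event peaks at its amplitude. Mixing the two conventions is a
deliberate choice: it makes both event amplitudes and sustained
self-induction levels directly comparable to the decoder's $h$ scale.

### Self-induction and individual differences

Volitional self-induction is a clipped mean-reverting AR(1) process:
from 0 toward an asymptote of $1.25 \times \text{controllability}$,
reversion rate 0.25 per TR, innovation SD 0.15 per TR, clipped to
$[-1.25, 1.25]$. Controllability in $[0,1]$ is the synthetic analogue of
BCI literacy; at intermediate values the process produces a realistic
mixture of criterion and emergency triggers. In cohorts, controllability
is coupled to the subject's unguided arousal-regulation slope, planting
the "unguided regulation predicts guided self-induction" effect.

### Psychophysiology

Trial-level corrugator EMG responds linearly to scaled valence and skin
conductance to scaled arousal (`simulate_physio()`), with unit response
noise. The *table-level* harness (`simulate_physio_table()`) instead
plants the validation model's own regression coefficient (score on
standardized response) — defaults 0.11 and 0.07 — because a
physiological gain and a regression coefficient only coincide for a
particular score variance; planting on the model's scale makes recovery
tests exact rather than approximate.

### What the generator does *not* emulate

Voxel noise is spatially independent: there is no smoothness, no
physiological confound structure, no motion. A consequence worth
stating: with independent noise, decodability is governed by the ratio
of labelled samples to voxels, so `simulate_study()` defaults to a
300-voxel "ROI" world where full-set cross-validated accuracy lands in
the high .50s–.60s — the regime of real-time affect decoders — while
`subject_profile()` keeps the configurable 2,000-voxel default for
container-scale work. A green end-to-end test establishes that the
machinery is correct on data satisfying the decoders' own linear
assumptions; it says nothing about robustness to realistic fMRI
artefacts.

## Stimulus machinery

Maximal-span sampling is greedy farthest-point dispersion on min-max
normalized valence–arousal coordinates (first pick nearest the centre of
the plane; ties broken by a seeded draw). Polar subsets start from the
valence tails ($v \ge 7$, $v \le 2.6$) and repeatedly shrink the
permissible arousal window by 0.1 Likert units per side toward the
pooled median until a two-sided rank-sum test no longer detects a group
arousal difference ($p > .05$); the catalog generator always embeds 30
arousal-matched interior items per tail so this procedure has a matched
core to settle on. Because the rank-sum test rejects matched pools at
its nominal rate, a given catalog can still collapse by chance;
`simulate_study()` regenerates the catalog (bounded, seed-derived
retries) rather than failing. Selected stimuli are split uniformly at
random into 40 Mod-PS and 20 Mod-FS trials, balanced by polarity.

## Decoding

* **Labels.** Volumes are labelled by thresholding the signed
  HRF-convolved score regressor at 20% of its maximum magnitude
  (`theta = 0.2`) — the threshold is unreported in the source design;
  0.2 excludes transition volumes while keeping plateau volumes, and is
  exposed in the interface.
* **Classifier.** L1-loss linear SVM, C = 1, solved by deterministic
  cyclic dual coordinate descent (no SVM dependency exists in the target
  environment, and the decoder is the scientific core, so it is
  implemented in-package with Rcpp). The bias is absorbed as an
  augmented regularized feature. Features are standardized per voxel
  with training statistics, folded back into the stored weights so
  `h = w·x + b` is affine in raw features.
* **Calibration.** Platt scaling with smoothed targets, fit by Newton
  iterations with backtracking. In the pipeline the coefficients are fit
  on *cross-validated* decision values: training margins of a
  near-separable SVM sit at ±1 and would saturate the probabilities.
* **Beta-series.** Least-squares-all: one design per run with one
  HRF-convolved unit regressor per event plus intercept and linear
  drift. Trials are spaced ≥ 4 s, which bounds but does not remove
  collinearity; rank-deficient designs error, naming the aliased events.
* **Reliable stimulus set.** Proxy criterion: mean inter-subject
  pairwise correlation of a stimulus' beta maps, keeping the top half.
  Per-stimulus amplitude gains in the generator make this set genuinely
  higher-SNR, reproducing the full-vs-reliable accuracy ordering
  qualitatively.

## The closed loop

Per volume: decode, detrend, display, test. Online detrending passes
raw values through before volume 40 of the run and afterwards subtracts
the OLS line fit to all previous distances. Feedback transparency is
the clipped affine map of $[-1.25, 1.25]$ onto $[0, 1]$, recomputed once
per volume (intra-TR animation is presentation-only). The consecutive
count is evaluated against the *time-varying* threshold during decay.
Criterion triggers present the stimulus one TR after the trigger volume
(fixed decode latency); the emergency default presents at the emergency
volume itself, so a 44-s trial (20 hold + 18 decay + 2 cue + 4 minimum
ITI) is always exactly accounted: trigger time + delay + cue + ITI =
trial length, with ITI ≥ the minimum in every path.

## Encoding maps

Decoder weights become encodings via the Haufe transform,
$\mathrm{Cov}(X)\,w / \mathrm{Var}(h)$, so whitened-feature decoders map
to their own weights. Group maps are voxelwise means. The permutation
null shuffles labels within subject, refits, re-transforms, and
re-averages; two-sided per-voxel p-values use the add-one rule
$(r+1)/(n+1)$. Whether the original test pooled voxels is ambiguous;
per-voxel is the default and a pooled variant is available via
`pooled = TRUE`.

## Statistics

`fit_mixed()` wraps `lme4::lmer` (ML, bobyqa): Wald t-tests with a
residual-df approximation ($n - p$), a *marginal* adjusted R² computed
on fixed-effect predictions (the source's R² definition for mixed
models is unspecified), and a likelihood-ratio test against the
fixed-effects-only linear model (boundary mixture makes it
conservative; tested as such). Continuous covariates are z-scored and
sex is coded ±0.5, so reported effects are on the standardized-covariate
scale while outcomes keep their native scale. Per-subject regulation
slopes/intercepts for downstream prediction are unpooled per-subject OLS
fits: mixed-model subject effects shrink to a common constant whenever
the random-slope variance is estimated at zero, which would alias the
induction-predictor design. That design's full 19-term interaction
structure is only identifiable for cohorts well above 19 subjects;
`run_study_analyses()` reduces it automatically for small cohorts
(`terms = "main"` or `"minimal"`).

### Calibration of the harnesses

The table-level generators plant exactly the quantities the acceptance
properties measure: self-induction bias δ = 0.033 on the probability
scale with carry-over 0.803 from the preceding volume and variances set
so the fitted marginal adjusted R² lands near 0.68–0.72; regulation
slope 0.33 with between-subject SD 0.1 and lag effect 0.01; physio
coefficients 0.11/0.07. Type-I error of the trial-type test is verified
in [0.025, 0.075] over 200 null replicates, and CI coverage ≥ 90% over
200 planted replicates.

One pipeline-level caveat: the preceding-volume and cue betas are
adjacent overlapping HRF regressors whose least-squares estimates are
*negatively* correlated under noise, so the fMRI-level pipeline does not
reproduce the large positive carry-over coefficient — that recovery is
a table-level property, and the ledgered limitation is inherent to
single-trial estimation, not a defect of the fit.

## Numerical choices and degenerate inputs

Seeded determinism everywhere (`seed` arguments; derived child seeds
stay below $2^{31}$); RNG state is restored after every seeded call.
The SVM solver sweeps cyclically (bit-reproducible refits) to a
projected-gradient tolerance of 1e-10; label flips negate the
hyperplane to solver tolerance. Onsets snap to the nearest volume
(always within TR/2). Constant decision values, single-class training
sets, empty held-out sets, collinear events, dimension mismatches, and
infeasible catalogs raise immediate, specific errors rather than
propagating NaNs. Singular mixed fits are flagged, not hidden.

## Known limitations

No spatial structure in noise; no NIfTI geometry or atlas space; no raw
psychophysiological waveforms (trial-level scalars only); no modelling
of reconstruction latency beyond the fixed one-TR delay; the
reliable-set criterion is a stated proxy for the original clustering
method; surrogate onsets are non-overlapping by design where the
original procedure is silent.
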