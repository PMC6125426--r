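---
title: "Modelling cued expectation bias in perceptual decisions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cued expectation bias in perceptual decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

In a probabilistic face/house discrimination task, each noise-degraded
stimulus movie is preceded by a cue announcing the prior probability of the
upcoming category (80% face, neutral, or 80% house; 20% of trials are
cue-only catch trials). Two distinct mechanisms could turn such a cue into
faster, more accurate decisions: a *pre-sensory* shift of the baseline
evidence towards the expected category, and a *post-sensory* change in how
efficiently the stimulus itself is accumulated. In the drift-diffusion
model (DDM) these correspond to the starting point `z` and the drift rate
`v`. On the neural side, predictive-coding accounts expect a cue-evoked
*prediction* signal in category-selective inferior temporal cortex that
scales with cued probability, followed by a stimulus-evoked
*prediction-error* signal that is larger for surprising than for expected
stimuli. This package implements both halves of that analysis — the
hierarchical Bayesian DDM comparison and the catch-trial FIR timecourse
machinery — plus a synthetic-data generator that reproduces the task design
so the entire pipeline runs, and is tested, without any external data.

# The decision model

The DDM accumulates noisy evidence `dX = v dt + s dW` between an upper and a
lower absorbing boundary separated by `a`. Throughout the package the
*upper boundary is the face response* and the *lower boundary the house
response*; drifts are signed (positive towards face) and the starting point
is relative, `z` in (0, 1), measured from the house boundary, so `z = 0.5`
is unbiased and `z > 0.5` is a face bias. The diffusion coefficient is
fixed at `s = 1`, which sets the scale of `a` and `v`. Boundaries are coded
by category rather than by accuracy so that an upwards starting-point shift
is interpretable as a face expectation.

The response-time likelihood is the Wiener first-passage-time (WFPT)
density. `wfpt_density()` evaluates the standard series representation with
the small-time/large-time switch chosen by the usual truncation-bound
comparison, at an absolute series error of `1e-7`. Inter-trial variability
follows the common three-parameter extension:

* `sv` — Gaussian drift variability, marginalized analytically (the
  Gaussian mixture over drifts has a closed form);
* `sz` — uniform starting-point range (a fraction of `a`), marginalized by
  7-point Gauss–Legendre quadrature;
* `st` — uniform non-decision-time range (s), also 7-point Gauss–Legendre.

The quadrature order was checked against 61-point quadrature (agreement to
machine precision on representative parameter sets; see the test suite).
Response times below the feasible minimum (`tr - st/2`) have zero density;
in `ddm_loglik()` such trials contribute a finite penalty of `-1e6` per
trial rather than `-Inf`, so MCMC proposals that momentarily step into an
infeasible region are rejected gracefully instead of crashing the sampler.

`simulate_ddm()` is the forward model: Euler–Maruyama integration with step
`dt = 1e-4` s by default (a coarser `1e-3` s is used for bulk posterior
predictive simulation). Because discretely monitored paths under-detect
boundary crossings, the simulator applies the Broadie–Glasserman–Kou
continuity correction (boundaries tested `0.5826 * sqrt(dt)` inside the
nominal ones); without it, absorption probabilities at `dt = 1e-4` are
biased by roughly two Monte-Carlo standard errors at `n = 1e5`, with it the
simulator agrees with the closed-form absorption probability
`P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))` to well within
sampling error. Trials whose response time would exceed the 6-s response
window are censored as `no_response`.

# The three cue-bias variants

`model_spec()` declares which parameters the cue may modulate:

* **PBM** (prior bias): starting points `z_f, z_n, z_h` vary by cue;
  drifts `v_F, v_H` depend only on the stimulus.
* **DBM** (dynamic bias): one starting point `z`; drifts `v_fF ... v_hH`
  vary by cue and stimulus.
* **MSM** (multi-stage): both sets free — PBM and DBM are nested inside it.

Every variant estimates boundary separation `a` and non-decision time `tr`
per subject. Inter-trial variability (`sv`, `sz`, `st`) is estimated at the
group level only: with a few hundred trials per subject these parameters
are not reliably identified per subject.

## Hierarchical structure and priors

Subject-level parameters are normal around group means, truncated to each
parameter's domain; group means and SDs get weakly informative priors:
`a ~ N(1.5, 1)` on (0, Inf); starting points `~ N(0.5, 0.25)` on
(0.05, 0.95); drifts `~ N(0, 2)`; `tr ~ N(0.3, 0.2)` on (0, 1); group SDs
half-normal with scale 0.5; `sv ~` half-normal(1), `sz ~ U(0, 0.4)`,
`st ~ U(0, 0.3)`. These are in the style of the widely used hierarchical
DDM toolboxes; the original settings behind the published fits are not
recoverable, so these defaults are declared substitutes and are fully
configurable through `default_priors()`.

## Sampling

`sample_posterior()` runs an adaptive Metropolis-within-Gibbs scheme:

* each subject-level parameter gets a Gaussian random-walk update whose
  scale adapts towards a 0.44 acceptance rate during burn-in and is frozen
  afterwards; per-cell log-likelihoods are cached so an update touches only
  the condition cells routed to that parameter;
* group means and SDs are updated conditionally on the subject values
  (no likelihood pass needed), with the truncated-normal normalizing
  constants included;
* the group variability parameters each require a full data pass and are
  updated round-robin, one per sweep;
* *group translation moves* propose shifting a group mean and every
  subject's value jointly for the starting-point and drift families. These
  counteract the hierarchical funnel: when a group SD is small, the
  subject-level values pin the group mean, and marginal updates mix poorly.

Convergence is summarized by split-half R-hat per parameter; any value
above 1.05 attaches a warning to the samples object rather than failing
silently. Two or more chains are recommended; the default configuration is
3 chains of 5,000 draws after 2,000 burn-in in `sample_posterior()`'s
upstream caller defaults, while the examples and tests use smaller,
explicitly stated settings.

## Model comparison and hypothesis tests

`compute_dic()` uses the Spiegelhalter plug-in convention: `D-bar` is the
posterior mean of `-2 log L` evaluated at the subject-level parameters, the
plug-in deviance is evaluated at the posterior mean of the subject-level
parameters (and of `sv`, `sz`, `st`, which enter the likelihood), and
`pD = D-bar - D(theta-bar)`, `DIC = D-bar + pD`. The plug-in choice matters
for `pD` and is therefore documented; a negative `pD` is reported with a
warning, never hidden. `compare_models()` ranks fits by DIC and flags
pairwise differences of 10 or more as decisive, the conventional threshold.

`posterior_probability()` computes directional hypothesis probabilities
such as `P(z_h < z_n)` from paired draws (same draw index within chain),
respecting posterior correlation rather than resampling independently.
Drift-rate hypotheses are evaluated on absolute values when requested, so
"faster" always means larger regardless of the house boundary's negative
sign coding.

`posterior_predict()` draws one retained posterior sample per subject per
dataset and forward-simulates datasets with the same per-condition trial
counts as the design — the basis of graphical posterior predictive checks
on condition means and RT quantiles.

# Behavioral statistics

**EWMA fast-guess filter.** Trials are sorted by ascending RT and an
exponentially weighted moving average of accuracy (weight `lambda = 0.01`)
is tracked from the chance baseline `p0 = 0.5`. Fast guesses keep the chart
near chance; once responses come under stimulus control it rises above the
control limit `p0 + L * sigma_t` (`L = 1.5`). The cutoff is the last RT at
which the chart still sits at or below the limit, and trials at or below
the cutoff are removed — but only when the chart actually signalled
guessing (dipped below the chance baseline) beforehand, so a dataset that
is accurate from its fastest trial onward loses nothing. The defaults
follow the control-chart settings popularized by the D-MAT toolbox and are
exposed because the original settings are not published. Note the
direction of the decision rule: a chart of accuracy over ascending RTs
*rises through an upper limit* when guessing stops; a lower limit cannot
detect guesses whose accuracy sits exactly at chance.

**Repeated-measures ANOVA.** `rm_anova_gg()` implements the fully
within-subject factorial ANOVA on orthonormal contrast scores, with the
Greenhouse–Geisser epsilon `(tr S)^2 / (q tr(S^2))` estimated from the
covariance of the contrast scores and corrected p-values from the F
distribution at epsilon-deflated degrees of freedom. A two-level factor has
epsilon exactly 1. The implementation is plain matrix algebra — partly so
the null-simulation property test (1,000 replicate ANOVAs) runs in seconds
— and is verified against `car::Anova`'s univariate GG output to 1e-8 in
the test suite.

**Pairwise comparisons** use paired t-tests with the Šidák family-wise
adjustment `1 - (1 - p)^m`. The adjustment never decreases a p-value and is
capped at 1.

# Catch-trial FIR analysis

`build_fir_design()` turns an event table into a delta-function design:
one regressor per event type per lag, time-locked one TR (1.5 s) *before*
the event onset, so lag 0 is a pre-onset anchor. The separated-events
variant has 3 cue regressors (cues from catch and full trials aggregated)
and 6 stimulus regressors (cue x stimulus), 12 lags each (108 columns);
the combined-events variant has 3 catch-cue regressors and 6 full-trial
regressors locked to cue onset, 14 lags each (126 columns); the fast/slow
variant recodes stimulus events by a per-subject median RT split
(`split_fast_slow()`; "fast" means faster than the median, trials exactly
at the median are dropped).

`fit_fir_glm()` estimates the responses by OLS with run-specific
intercepts. Signals are converted to percent signal change about the run
mean — the unmodelled timepoints form the implicit baseline of an FIR
model, and the run mean stands in for a scanner-specific intensity
normalization, which is out of scope here. On noise-free series constructed
as `design %*% coefficients` the estimates are exact to numerical
precision (`psc = FALSE`).

**Peak rule.** The peak magnitude of an estimated timecourse is the
maximum over post-onset lags, excluding the lag-0 anchor, ties resolved to
the earliest lag (`extract_peak()`). A single-lag maximum was chosen over
windowed means for transparency and testability; no published definition
was available to match.

**Separability.** `regressor_separability()` reports the maximum absolute
correlation between cue- and stimulus-regressor columns plus a
variance-inflation summary, and can compare two designs on the same
timebase. The catch-trial + jittered design yields strictly lower
cue/stimulus collinearity than the same schedule with no catch trials and
no jitter — the design's reason for existing, and a deterministic test.

**ROI growing.** `localize_rois()` smooths a 3-D Z map with a 4-mm-FWHM
Gaussian (separable kernel, zero-padded edges), finds strict 26-neighbour
local maxima above +1.96 (labelled *face*) and minima below -1.96
(labelled *house*), enforces a minimum peak separation equal to the 8-mm
sphere radius (greedy, by descending |Z|), grows spheres, and drops voxels
that do not exceed the threshold with matching sign in the *original*
unsmoothed map. Anatomical masking is replaced by label-by-sign on
synthetic maps; atlases are out of scope.

**Prediction/surprise decomposition.** `fit_pc_decomposition()` fits the
six condition peaks as `baseline + w_P * P(preferred | cue) + w_S *
surprise`, where the surprise term is `1 - P(presented stimulus | cue)` on
preferred-stimulus trials and 0 otherwise, by least squares. This linear
form is this package's operationalization — the original specification of
the unit decomposition was not available — and the surprise:prediction
weight ratio is the summary of interest. The design is identifiable
whenever the cue probabilities differ.

# The synthetic-data generator

`generate_design()` reproduces the printed design exactly for any seed:
600 trials per subject in 5 runs of 120; 200 trials per cue with 40
catch trials each (20% overall); 128 valid / 32 invalid full trials per
80% cue and 80/80 for the neutral cue; 3-s cue phase; 6-s task phase fixed
at the end of the cue phase (un-jittered); rest periods at TR multiples in
[0, 15] s. The published schedules were produced by a covariance-minimizing
sequence optimizer; that optimizer is not reproduced. Instead rest periods
are drawn from a truncated geometric distribution on TR multiples
calibrated so the mean rest is 1.92 s, and `regressor_separability()` is
available to verify that a generated schedule separates cue from stimulus
regressors adequately.

`default_ground_truth()` encodes the generative group effects the models
are meant to detect, with the neutral starting point anchored at 0.66 —
the one starting-point value printed for the original data — and the rest
chosen once as plausible for a noise-degraded discrimination with ~67%
noise: `a = 1.6`, `tr = 0.6` s, `z = (0.72, 0.66, 0.58)` for face/
neutral/house cues (all above the midpoint, reflecting the general face
bias), face drifts ~1.0 essentially unmodulated by cue, house drifts
stronger in magnitude (-1.2 to -1.25) but attenuated to -0.85 after face
cues. Between-subject SDs (0.15, 0.08, 0.04, 0.15 for `a`, `tr`, `z`, `v`)
and group variability (`sv = 0.4`, `sz = 0.06`, `st = 0.15`) are of the
magnitude typical for this class of task.

`synthesize_bold()` builds ROI-averaged BOLD as amplitude-scaled
double-gamma HRFs at every cue and stimulus onset plus AR(1) noise and a
linear drift around a baseline of 100. The default amplitudes describe a
face-preferring region whose cue response scales with cued face
probability (prediction weight 0.25) and whose stimulus responses scale
with surprise (weight 0.5) — i.e. a 2:1 surprise-to-prediction ratio, the
ratio reported for this decomposition in the literature — yielding the
cue ordering house < neutral < face and expectation suppression
(expected < unexpected) that the FIR recovery tests check.

`generate_stimulus_movie()` renders the 6-s dynamic stimulus: a
procedurally drawn face-like or house-like 512 x 512 pattern (the original
photographic sets are licensed and are not redistributed; the category here
is a label, not a perceptual claim), standardized and mixed per frame as
`sqrt(1-w) * image + sqrt(w) * noise` so that noise carries exactly the
fraction `w` (default 0.67) of pixel variance — the package's
operationalization of "67% noise", since the original report pins the SNR
verbally but not by formula. The noise field is independent across the 90
frames while the per-frame SNR is constant.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: real BOLD noise structure (physiological
fluctuations, motion, spatially correlated noise), anatomical variability
and registration error, sequence-optimized trial orderings, perceptual
properties of the stimuli, attentional lapses and contaminant RTs beyond
fast guesses, and any misspecification of the DDM itself. Recovery results
demonstrate that the estimation machinery is correct under its own
assumptions, not that those assumptions hold in any particular dataset.

# Numerical and testing choices

* WFPT series error `1e-7`; quadrature 7-point Gauss–Legendre per
  variability dimension; zero-density penalty `-1e6` per trial.
* Euler step `1e-4` s (simulation oracles), `1e-3` s (bulk posterior
  predictive); Broadie–Glasserman–Kou boundary correction always on.
* Ties in the EWMA RT sort are broken by original trial order (stable
  sort); duplicating every trial changes the chart's step count, so the
  removal fraction is only approximately invariant under duplication and
  is tested with a 2-point tolerance.
* Sampling-based tests run at reduced problem sizes chosen once: the
  parameter-recovery study uses 10 replicates of 12 synthetic subjects with
  300 trials each (the full condition structure at half the trial count)
  and single chains of 700 retained draws after 500 burn-in sweeps; model
  identification uses 8 subjects x 120 trials with 2 chains; the
  conjugate-oracle and determinism checks use toy sizes. The end-to-end
  pipeline default (`run_config()`) is likewise a quick desk-scale
  configuration, with production settings documented on the arguments.
* The hierarchical fits drop `no_response` trials; the likelihood is not
  truncated for the 6-s deadline. At the generative settings the censoring
  rate is well below 1%, but fits to data with heavy censoring would be
  biased — a known limitation.
* Posterior intervals in the recovery tests are equal-tailed 95% credible
  intervals from modest MCMC runs; their frequentist coverage of the
  generating group means is checked in aggregate (at least 90% across
  parameters and replicates), not per parameter, because single short
  chains make individual interval endpoints noisy.

# Known limitations

* The sampler is random-walk based; posteriors with strong funnel geometry
  mix slowly even with the translation moves, and very small group SDs can
  still bias short runs. For publication-grade fits, run several thousand
  draws across 3+ chains and check the attached R-hat values.
* DIC with the plug-in at the subject-level posterior mean is the
  convention implemented; alternatives (WAIC, LOO) are out of scope.
* The FIR design assumes onsets on the TR grid (the task design guarantees
  this); arbitrary-onset designs would need finer time binning.
* The prediction/surprise decomposition has three free parameters for six
  condition means; it is a summary fit, not a process model.
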