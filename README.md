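# cueddm

Hierarchical drift-diffusion modelling of cued expectation bias, with
catch-trial FIR analysis of ROI-averaged BOLD time series.

## What this package is for

In cued perceptual decision tasks — here, a probabilistic face/house
discrimination in which each noise-degraded stimulus movie is preceded by a
cue announcing the prior probability of the upcoming category (80% face,
neutral, 80% house) — prior knowledge can act at two distinct stages:
*before* the stimulus, by shifting the baseline of evidence accumulation,
and *after* stimulus onset, by changing the rate at which sensory evidence
accrues. The package is for researchers who want to separate those two
mechanisms computationally and relate them to cue- and stimulus-evoked
fMRI activity in category-selective cortex.

The core is the drift-diffusion model (DDM): evidence `X(t)` accumulates as
`dX = v dt + dW` between absorbing boundaries at `0` (house response) and
`a` (face response), starting at `z·a` with relative starting point
`z ∈ (0,1)`; the response time is the first-passage time plus a
non-decision time `tr`, with inter-trial variability `sv` (drift), `sz`
(starting point) and `st` (non-decision time). Three hierarchical Bayesian
variants encode where probabilistic cues may act:

| model | cue modulates | free per subject |
|-------|----------------|------------------|
| PBM   | starting point | `z_f, z_n, z_h` + `v_F, v_H` |
| DBM   | drift rate     | `z` + `v_fF … v_hH` |
| MSM   | both           | `z_f, z_n, z_h` + `v_fF … v_hH` |

Fits are compared by DIC (`DIC = D̄ + pD`, decisive at a gap of 10 or
more), condition effects are tested as posterior probabilities of ordered
parameters such as `P(z_h < z_n)`, and model adequacy is checked by
posterior predictive simulation with trial counts matched to the design.

Around the model sit the standard analysis stages: an EWMA control-chart
filter for fast guesses, Greenhouse–Geisser-corrected repeated-measures
ANOVA and Šidák-corrected pairwise tests, finite-impulse-response (FIR)
deconvolution of cue- and stimulus-evoked BOLD timecourses from a
catch-trial design (with design-separability diagnostics), spherical ROI
growing on statistical maps, and a prediction/surprise decomposition of
event-related peaks. A synthetic-data module regenerates the complete task
— trial counts, timing, jitter, DDM behavior, ROI BOLD series, stimulus
movies, statistical maps — so every stage runs end to end with no external
data.

## Worked example

```r
library(cueddm)

# one synthetic session per subject, at the printed task design:
# 600 trials in 5 runs, 200 per cue, 20% catch, 128/32 validity split
design <- generate_design(design_config(), seed = 1)
truth  <- default_ground_truth(n_subjects = 6, seed = 1)
beh    <- simulate_behavior(design, truth, seed = 1)
beh    <- beh[beh$response != "no_response", ]

# fast-guess filtering, then fit the multi-stage bias model
beh <- ewma_filter(beh)$data
fit <- fit_hddm(beh, model = "MSM", chains = 2, draws = 400, burnin = 400,
                seed = 1)
print(fit)
```

```
Hierarchical MSM drift-diffusion fit
  6 subjects, 2880 trials; 2 chains x 400 draws
MSM: DIC = 2892.16 (Deviance = 2847.98, pD = 44.18)
Group means:
   mu_a   mu_tr  mu_z_f  mu_z_n  mu_z_h mu_v_fF mu_v_fH mu_v_nF mu_v_nH mu_v_hF 
  1.567   0.663   0.703   0.616   0.580   1.186  -0.793   0.929  -1.191   0.961 
mu_v_hH 
 -1.352 
```

(At this deliberately short chain length the sampler also warns that R-hat
exceeds 1.05 for some parameters; increase `draws`/`burnin` for real use.)

The group means recover the generating values: starting points ordered
`z_h < z_n < z_f` and all above the 0.5 midpoint (a general face bias whose
strength follows the cue), face drifts near 1 regardless of cue, and house
drifts (negative: towards the lower boundary) weakened after a face cue.
Directional hypotheses are posterior probabilities over paired draws:

```r
posterior_probability(fit, "z_h", "z_n", "<")     # house cue lowers z
posterior_probability(fit, "v_fH", "v_nH", "<",   # face cue slows house drift
                      absolute = TRUE)
```

```
[1] 0.86375
[1] 0.98875
```

`simulate(fit, nsim = 100)` produces posterior predictive datasets with
matched condition counts; `fit_hddm(beh, "PBM")` / `"DBM"` fit the
restricted variants and `compare_models()` ranks the three by DIC. For the
imaging side, `build_fir_design()`, `fit_fir_glm()`, `extract_peak()`,
`regressor_separability()`, `localize_rois()` and `fit_pc_decomposition()`
implement the catch-trial FIR pipeline; `run_pipeline(run_config())`
executes the whole chain and writes per-stage artifacts plus a manifest.

See the methods vignette (`vignettes/cueddm-methods.Rmd`) for the model
conventions, priors, sampler design, and every place a published detail was
under-specified and a documented choice was made.

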