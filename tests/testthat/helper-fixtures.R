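# Shared fixtures, generated in code. A scaled-down version of the task
# design keeps the condition structure (3 cues x 2 stimuli, 20% catch
# trials, 80% validity) at a fraction of the trial count so sampling-based
# tests stay fast.

scaled_design_config <- function(mult = 1) {
  design_config(n_runs = 2, trials_per_run = 60 * mult,
                trials_per_cue = 40 * mult, catch_per_cue = 8 * mult,
                valid_trials = 26 * mult, invalid_trials = 6 * mult,
                neutral_face = 16 * mult, neutral_house = 16 * mult)
}

make_behavior <- function(n_subjects = 4, seed = 1, mult = 1) {
  des <- generate_design(scaled_design_config(mult), seed = seed)
  truth <- default_ground_truth(n_subjects = n_subjects, seed = seed + 1)
  beh <- simulate_behavior(des, truth, seed = seed + 2, dt = 2e-4)
  list(design = des, truth = truth,
       behavior = beh[beh$response != "no_response", ])
}

# ground truth with PBM structure: drifts shared across cues within subject
make_pbm_truth <- function(n_subjects, seed = 1,
                           z = c(f = 0.72, n = 0.66, h = 0.58),
                           vF = 1.1, vH = -1.2) {
  truth <- default_ground_truth(n_subjects = n_subjects, seed = seed,
                                group_means = list(a = 1.6, tr = 0.6, z = z,
                                                   v = c(fF = vF, nF = vF,
                                                         hF = vF, fH = vH,
                                                         nH = vH, hH = vH)))
  for (s in seq_along(truth$subjects)) {
    v <- truth$subjects[[s]]$v
    truth$subjects[[s]]$v <- c(fF = v[["nF"]], nF = v[["nF"]],
                               hF = v[["nF"]], fH = v[["nH"]],
                               nH = v[["nH"]], hH = v[["nH"]])
  }
  truth
}

# one small hierarchical fit shared across test files (memoized)
.fixture_env <- new.env(parent = emptyenv())

small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    bd <- make_behavior(n_subjects = 4, seed = 7)
    .fixture_env$data <- bd
    .fixture_env$fit <- suppressWarnings(
      fit_hddm(bd$behavior, "MSM", chains = 2, draws = 150, burnin = 150,
               seed = 11))
  }
  .fixture_env$fit
}

small_fit_data <- function() {
  small_fit()
  .fixture_env$data
}

# hand-built posterior container for tests of draw-based utilities
fake_samples <- function(draws_list, deviance = NULL) {
  structure(list(chains = draws_list,
                 deviance = deviance,
                 param_names = colnames(draws_list[[1]]),
                 types = character(), subjects = integer(),
                 model_name = "fake",
                 rhat = stats::setNames(rep(1, ncol(draws_list[[1]])),
                                        colnames(draws_list[[1]])),
                 convergence_warning = NULL,
                 config = list()),
            class = "hddm_samples")
}
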