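test_that("model specifications route parameters to condition cells", {
  msm <- model_spec("MSM")
  expect_setequal(msm$subject_types,
                  c("a", "tr", "z_f", "z_n", "z_h",
                    "v_fF", "v_nF", "v_hF", "v_fH", "v_nH", "v_hH"))
  pbm <- model_spec("PBM")
  expect_setequal(pbm$subject_types,
                  c("a", "tr", "z_f", "z_n", "z_h", "v_F", "v_H"))
  dbm <- model_spec("DBM")
  expect_equal(sum(startsWith(dbm$subject_types, "z")), 1)
  expect_equal(sum(startsWith(dbm$subject_types, "v")), 6)
  # PBM/DBM are restrictions of the MSM: same cells, nested routing
  expect_identical(msm$cells, pbm$cells)
  expect_identical(msm$cell_map$fF, c(z = "z_f", v = "v_fF"))
  expect_identical(pbm$cell_map$fF, c(z = "z_f", v = "v_F"))
  expect_identical(dbm$cell_map$fF, c(z = "z", v = "v_fF"))
})

test_that("build_model does the bookkeeping and validates cells", {
  bd <- make_behavior(n_subjects = 2, seed = 3)
  m <- build_model(bd$behavior, "MSM")
  expect_equal(length(m$subj_names), 2 * 11)
  expect_equal(sum(grepl("^z_", m$subj_names)), 6)   # 3 z per subject
  expect_equal(sum(grepl("^v_", m$subj_names)), 12)  # 6 v per subject
  mp <- build_model(bd$behavior, "PBM")
  expect_equal(sum(grepl("^z_", mp$subj_names)), 6)
  expect_equal(sum(grepl("^v_", mp$subj_names)), 4)  # v_F, v_H per subject

  broken <- bd$behavior[!(bd$behavior$subj_idx == 2 &
                            bd$behavior$cue == "80H" &
                            bd$behavior$stim == "face"), ]
  expect_error(build_model(broken, "MSM"), "subject 2.*hF")
})

test_that("log-posterior decomposes into prior plus summed likelihoods", {
  bd <- make_behavior(n_subjects = 2, seed = 3)
  m <- build_model(bd$behavior, "MSM")
  types <- m$spec$subject_types
  group <- c(stats::setNames(
    vapply(types, function(p) switch(substr(p, 1, 1),
                                     a = 1.5, t = 0.5, z = 0.6,
                                     v = if (endsWith(p, "H")) -1 else 1), 0),
    paste0("mu_", types)),
    stats::setNames(rep(0.1, length(types)), paste0("sigma_", types)),
    sv = 0.3, sz = 0.05, st = 0.1)
  group <- as.list(group)
  subj <- matrix(rep(unlist(group[paste0("mu_", types)]), each = 2),
                 nrow = 2, dimnames = list(NULL, types))
  subj[2, "z_f"] <- 0.68; subj[2, "a"] <- 1.7

  lp <- m$log_posterior(group, subj)
  # independent recomposition through the public likelihood
  ll <- 0
  for (s in 1:2) {
    d <- bd$behavior[bd$behavior$subj_idx == s, ]
    for (cue in c("80F", "50N", "80H")) for (st in c("face", "house")) {
      i <- d$cue == cue & d$stim == st
      cl <- paste0(c(`80F` = "f", `50N` = "n", `80H` = "h")[cue],
                   c(face = "F", house = "H")[st])
      p <- ddm_params(a = subj[s, "a"],
                      z = subj[s, paste0("z_", substr(cl, 1, 1))],
                      v = subj[s, paste0("v_", cl)],
                      tr = subj[s, "tr"], sv = group$sv, sz = group$sz,
                      st = group$st)
      ll <- ll + ddm_loglik(d$rt[i], d$response[i] == "face", p)
    }
  }
  expect_equal(lp, m$log_prior(group, subj) + ll, tolerance = 1e-8)
})

test_that("sampler is seed-deterministic and matches a conjugate oracle", {
  bd <- make_behavior(n_subjects = 2, seed = 3)
  m <- build_model(bd$behavior, "PBM")
  s1 <- suppressWarnings(sample_posterior(m, chains = 1, draws = 30,
                                          burnin = 20, seed = 5))
  s2 <- suppressWarnings(sample_posterior(m, chains = 1, draws = 30,
                                          burnin = 20, seed = 5))
  expect_identical(s1$chains, s2$chains)

  # known-variance normal model: posterior for the group mean is available
  # in closed form
  set.seed(8)
  zs <- rnorm(12, 0.64, 0.05)
  m0 <- 0.5; s0 <- 0.25; tau <- 0.05
  post_var <- 1 / (1 / s0^2 + length(zs) / tau^2)
  post_mean <- post_var * (m0 / s0^2 + sum(zs) / tau^2)
  logpost <- function(mu) sum(dnorm(zs, mu, tau, log = TRUE)) +
    dnorm(mu, m0, s0, log = TRUE)
  draws <- cueddm:::rw_metropolis(function(x) logpost(x[1]), 0.5,
                                  n = 20000, proposal_sd = 0.02, seed = 2,
                                  burnin = 2000)
  expect_lt(abs(mean(draws) - post_mean), 3 * sqrt(post_var) / sqrt(500))
  expect_lt(abs(sd(draws) - sqrt(post_var)), 0.25 * sqrt(post_var))
})

test_that("DIC identity holds and the point-mass posterior gives pD = 0", {
  pbm <- fit_result(26593.57, 130.30, "PBM")
  expect_equal(pbm$dic, 26723.87, tolerance = 1e-9)
  msm <- fit_result(26448.90, 206.02, "MSM")
  expect_equal(msm$dic, 26654.92, tolerance = 1e-9)
  expect_equal(pbm$dic - pbm$deviance_bar - pbm$pd, 0)
  expect_warning(fit_result(100, -5), "negative pD")

  fit <- small_fit()
  d <- fit$dic
  expect_equal(d$dic - d$deviance_bar - d$pd, 0)

  # degenerate posterior: every draw identical
  samples <- fit$samples
  model <- fit$model
  row1 <- samples$chains[[1]][1, , drop = FALSE]
  deg <- samples
  for (ch in seq_along(deg$chains)) {
    deg$chains[[ch]] <- row1[rep(1, nrow(samples$chains[[ch]])), ,
                             drop = FALSE]
    colnames(deg$chains[[ch]]) <- colnames(row1)
    subj <- matrix(row1[1, model$subj_names], nrow = model$n_subjects,
                   byrow = TRUE,
                   dimnames = list(NULL, model$spec$subject_types))
    dev_pt <- -2 * model$log_likelihood(subj, row1[1, c("sv", "sz", "st")])
    deg$deviance[[ch]] <- rep(dev_pt, nrow(deg$chains[[ch]]))
  }
  dd <- compute_dic(deg, model)
  expect_equal(dd$pd, 0, tolerance = 1e-6)
  expect_equal(dd$dic, dd$deviance_bar, tolerance = 1e-6)
})

test_that("posterior hypothesis tests behave on degenerate and normal draws", {
  x <- matrix(c(rep(0.4, 100), rep(0.6, 100)), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  s <- fake_samples(list(x))
  expect_equal(posterior_probability(s, "A", "A", "<"), 0)
  expect_equal(posterior_probability(s, "A", "B", "<"), 1)

  set.seed(4)
  n <- 1e5
  m <- cbind(A = rnorm(n, 0, 1), B = rnorm(n, 0.5, 1))
  s2 <- fake_samples(list(m))
  expect_equal(posterior_probability(s2, "A", "B", "<"),
               pnorm(0.5 / sqrt(2)), tolerance = 0.01)
  # jittered self-comparison is symmetric
  m3 <- cbind(A = rnorm(n), B = rnorm(n))
  expect_equal(posterior_probability(fake_samples(list(m3)), "A", "B", "<"),
               0.5, tolerance = 0.01)
  # absolute-value comparison flips sign-coded drifts
  m4 <- cbind(vF = rep(1, 50), vH = rep(-2, 50))
  s4 <- fake_samples(list(m4))
  expect_equal(posterior_probability(s4, "vF", "vH", "<"), 0)
  expect_equal(posterior_probability(s4, "vF", "vH", "<", absolute = TRUE), 1)
  expect_error(posterior_probability(s4, "vF", "nope"), "unknown")
})

test_that("model comparison ranks by DIC with the 10-point rule", {
  fits <- list(fit_result(26593.57, 130.30, "PBM"),
               fit_result(26666.99, 41.34, "DBM"),
               fit_result(26448.90, 206.02, "MSM"))
  cmp <- compare_models(fits)
  expect_equal(cmp$winner, "MSM")
  expect_equal(cmp$ranking$model, c("MSM", "DBM", "PBM"))
  off <- cmp$significant[upper.tri(cmp$significant)]
  expect_true(all(off))

  near <- compare_models(list(fit_result(90, 10, "m1"),
                              fit_result(95, 10, "m2")))
  expect_equal(near$winner, "m1")
  expect_false(near$significant["m1", "m2"])
  edge <- compare_models(list(fit_result(90, 10, "m1"),
                              fit_result(100, 10, "m2")))
  expect_true(edge$significant["m1", "m2"])  # threshold is inclusive

  f1 <- fit_result(100, 5, "a", checksum = list(n = 10, sum_rt = 1))
  f2 <- fit_result(90, 5, "b", checksum = list(n = 11, sum_rt = 2))
  expect_error(compare_models(list(f1, f2)), "different datasets")
})

test_that("the MSM log-likelihood matches its restrictions at nested points", {
  bd <- make_behavior(n_subjects = 2, seed = 5)
  msm <- build_model(bd$behavior, "MSM")
  pbm <- build_model(bd$behavior, "PBM")
  varp <- c(sv = 0.3, sz = 0.05, st = 0.1)
  subj_pbm <- matrix(c(1.5, 0.5, 0.7, 0.65, 0.58, 1, -1.1,
                       1.6, 0.45, 0.72, 0.66, 0.6, 0.9, -1.2),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(NULL, pbm$spec$subject_types))
  # embed the PBM point in MSM coordinates (drifts equal across cues)
  subj_msm <- cbind(subj_pbm[, c("a", "tr", "z_f", "z_n", "z_h")],
                    matrix(subj_pbm[, "v_F"], 2, 3),
                    matrix(subj_pbm[, "v_H"], 2, 3))
  colnames(subj_msm) <- c("a", "tr", "z_f", "z_n", "z_h",
                          "v_fF", "v_nF", "v_hF", "v_fH", "v_nH", "v_hH")
  expect_equal(msm$log_likelihood(subj_msm, varp),
               pbm$log_likelihood(subj_pbm, varp), tolerance = 1e-10)
})

test_that("posterior predictive datasets match requested condition counts", {
  fit <- small_fit()
  bd <- small_fit_data()
  pp <- posterior_predict(fit, design = bd$design, n_datasets = 2, seed = 3,
                          keep_datasets = TRUE)
  cfg <- attr(bd$design, "config")
  for (ds in pp$datasets) {
    for (s in fit$model$subjects) {
      d <- ds[ds$subj_idx == s, ]
      expect_equal(sum(d$cue == "80F" & d$stim == "face"), cfg$valid_trials)
      expect_equal(sum(d$cue == "80F" & d$stim == "house"),
                   cfg$invalid_trials)
      expect_equal(sum(d$cue == "50N" & d$stim == "face"), cfg$neutral_face)
    }
  }
  expect_true(all(c("accuracy", "mean_rt_correct") %in%
                    names(pp$summaries)))
  expect_true(all(pp$quantiles$rt > 0))
})

test_that("point-mass parameters leave only simulation noise across datasets", {
  fit <- small_fit()
  deg <- fit
  row1 <- fit$samples$chains[[1]][1, , drop = FALSE]
  for (ch in seq_along(deg$samples$chains)) {
    n <- nrow(deg$samples$chains[[ch]])
    deg$samples$chains[[ch]] <- row1[rep(1, n), , drop = FALSE]
    colnames(deg$samples$chains[[ch]]) <- colnames(row1)
  }
  pp <- posterior_predict(deg, n_datasets = 20, seed = 9)
  cell <- pp$summaries[pp$summaries$cue == "80F" & pp$summaries$stim == "face", ]
  # binomial simulation noise: SD of the mean accuracy across datasets
  n_cell <- cell$n[1]
  p <- mean(cell$accuracy)
  expect_lt(sd(cell$accuracy), 3 * sqrt(p * (1 - p) / n_cell))
})
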