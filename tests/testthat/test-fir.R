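make_events <- function() {
  generate_design(scaled_design_config(), seed = 4)
}

test_that("FIR designs have the expected shape and delta placement", {
  ev <- make_events()
  sep <- build_fir_design(ev, "separated")
  expect_equal(ncol(sep$X), 9 * 12)
  expect_equal(sort(unique(sep$labels$event_type)),
               sort(c(paste0("cue_", c("f", "n", "h")),
                      paste0("stim_", c("fF", "nF", "hF", "fH", "nH",
                                        "hH")))))
  comb <- build_fir_design(ev, "combined")
  expect_equal(ncol(comb$X), 9 * 14)
  expect_true(all(sep$X %in% c(0, 1)))
  # each event contributes exactly one 1 per lag column
  expect_true(all(colSums(sep$X[, startsWith(colnames(sep$X), "cue_f"),
                                drop = FALSE]) == sum(ev$cue == "80F")))
  expect_true(all(colSums(sep$X[, startsWith(colnames(sep$X), "stim_nH"),
                                drop = FALSE]) ==
                    sum(ev$cue == "50N" & ev$stimulus == "house")))

  # single event: lag-k column has its 1 at index(onset) - 1 + k
  one <- data.frame(onset = 9, duration = 3, run = 1, trial_kind = "catch",
                    cue = "80F", stimulus = "none")
  d1 <- build_fir_design(one, "separated", run_lengths = 40)
  tp <- round(9 / 1.5) + 1
  for (k in 0:11)
    expect_equal(which(d1$X[, paste0("cue_f.lag", k)] == 1), tp - 1 + k)

  too_late <- data.frame(onset = 55, duration = 3, run = 1,
                         trial_kind = "catch", cue = "80F",
                         stimulus = "none")
  expect_error(build_fir_design(too_late, "separated", run_lengths = 40),
               "past the run end")
  dup <- rbind(one, one)
  expect_error(build_fir_design(dup, "separated", run_lengths = 40),
               "duplicate")
})

test_that("OLS recovers noise-free coefficients exactly and nulls are flat", {
  ev <- make_events()
  des <- build_fir_design(ev, "separated")
  set.seed(5)
  beta <- rnorm(ncol(des$X))
  rl <- des$run_lengths
  y <- as.vector(des$X %*% beta) + rep(c(5, 9), rl)
  yl <- split(y, rep(seq_along(rl), rl))
  fit <- fit_fir_glm(yl, des, psc = FALSE)
  lab <- paste0(fit$timecourses$condition, ".lag", fit$timecourses$lag)
  expect_equal(fit$timecourses$estimate, beta[match(lab, colnames(des$X))],
               tolerance = 1e-8)

  set.seed(6)
  ynull <- lapply(rl, function(n) rnorm(n, 100, 0.5))
  fit0 <- fit_fir_glm(ynull, des)
  expect_true(all(abs(fit0$timecourses$estimate) <=
                    3.9 * fit0$timecourses$se))

  # duplicated column is reported by name
  des_bad <- des
  des_bad$X <- cbind(des$X, des$X[, 1, drop = FALSE])
  des_bad$labels <- rbind(des$labels, des$labels[1, ])
  colnames(des_bad$X)[ncol(des_bad$X)] <- "dup.lag0"
  expect_error(fit_fir_glm(ynull, des_bad), "collinear")
})

test_that("generated cue and stimulus amplitude orderings are recovered", {
  # full-size session: 200 events per cue type keep peak noise well below
  # the generated amplitude gaps
  ev <- generate_design(design_config(), seed = 12)
  bo <- synthesize_bold(ev, bold_config(), seed = 12)
  des <- build_fir_design(ev, "separated")
  fit <- fit_fir_glm(bo$series, des)
  pk <- setNames(fit$peaks$peak, fit$peaks$condition)
  # cue ordering house < neutral < face, as generated
  expect_lt(pk[["cue_h"]], pk[["cue_n"]])
  expect_lt(pk[["cue_n"]], pk[["cue_f"]])
  # expectation suppression: expected < unexpected stimulus responses
  expect_lt(pk[["stim_fF"]], pk[["stim_hF"]])
  expect_lt(pk[["stim_hH"]], pk[["stim_fH"]])

  # combined- and separated-events cue estimates agree on common data
  comb <- fit_fir_glm(bo$series, build_fir_design(ev, "combined"))
  pc <- setNames(comb$peaks$peak, comb$peaks$condition)
  sep_cue <- pk[paste0("cue_", c("f", "n", "h"))]
  comb_cue <- pc[paste0("catchcue_", c("f", "n", "h"))]
  expect_gt(cor(sep_cue, comb_cue), 0.9)
})

test_that("peak extraction ignores the pre-onset anchor and breaks ties", {
  expect_equal(extract_peak(c(0, 0.1, 0.5, 0.3)),
               list(magnitude = 0.5, lag = 2L))
  expect_equal(extract_peak(rep(0, 12)), list(magnitude = 0, lag = 1L))
  expect_equal(extract_peak(c(9, 1, 1, 1))$lag, 1L)  # anchor excluded
  expect_error(extract_peak(numeric(0)), "empty")

  # double-gamma response sampled at the TR: peak magnitude ~ amplitude
  tc <- 0.8 * hrf_double_gamma((0:11 - 1) * 1.5)
  pk <- extract_peak(tc)
  expect_equal(pk$magnitude, 0.8, tolerance = 0.05)
})

test_that("separability flags orthogonal, identical, and degenerate designs", {
  ev <- make_events()
  des <- build_fir_design(ev, "separated")
  rep1 <- regressor_separability(des)
  expect_true(rep1$max_cue_stim_cor < 1)
  expect_false(rep1$singular)
  expect_true(all(rep1$vif[is.finite(rep1$vif)] >= 1))

  # orthogonal toy design
  toy <- des
  toy$X <- cbind(diag(10), rbind(matrix(0, 5, 10), diag(10)[1:5, ]))[, 1:12]
  toy$X <- matrix(0, 20, 4)
  toy$X[1, 1] <- toy$X[5, 2] <- toy$X[9, 3] <- toy$X[13, 4] <- 1
  colnames(toy$X) <- c("cue_f.lag0", "cue_n.lag0", "stim_fF.lag0",
                       "stim_fH.lag0")
  toy$labels <- data.frame(event_type = c("cue_f", "cue_n", "stim_fF",
                                          "stim_fH"), lag = 0L)
  toy$run <- rep(1, 20)
  rep_o <- regressor_separability(toy)
  expect_equal(rep_o$max_cue_stim_cor, max(abs(cor(toy$X)[1:2, 3:4])))

  # identical cue and stimulus columns: singular, VIF flagged infinite
  same <- toy
  same$X[, 3] <- same$X[, 1]
  rep_s <- regressor_separability(same)
  expect_equal(rep_s$max_cue_stim_cor, 1)
  expect_true(rep_s$singular)
  expect_true(any(is.infinite(rep_s$vif)))

  # catch trials + jitter strictly beat a no-catch, un-jittered schedule
  cfg0 <- design_config(n_runs = 2, trials_per_run = 60, trials_per_cue = 40,
                        catch_per_cue = 0, valid_trials = 32,
                        invalid_trials = 8, neutral_face = 20,
                        neutral_house = 20, jitter_max = 0, jitter_mean = 0)
  degen <- build_fir_design(generate_design(cfg0, seed = 4), "separated")
  cmp <- regressor_separability(des, reference = NULL)
  expect_lt(cmp$max_cue_stim_cor,
            regressor_separability(degen)$max_cue_stim_cor)
})

test_that("fast/slow median split drops ties and orders means", {
  ev <- data.frame(trial_kind = "full", rt = c(1, 2, 3, 4), accuracy = 1,
                   onset = c(3, 18, 33, 48), duration = 9, run = 1,
                   cue = "50N", stimulus = "face")
  sp <- split_fast_slow(ev)
  expect_equal(sp$speed, c("fast", "fast", "slow", "slow"))

  odd <- ev[c(1, 2, 3, 4, 4), ]
  odd$rt <- c(1, 2, 3, 4, 5)
  sp2 <- split_fast_slow(odd)
  expect_true(is.na(sp2$speed[3]))  # the median trial is dropped
  expect_equal(sum(sp2$speed == "fast", na.rm = TRUE), 2)

  bd <- make_behavior(n_subjects = 2, seed = 13)
  beh <- bd$behavior[bd$behavior$accuracy == 1, ]
  beh$trial_kind <- "full"
  sp3 <- split_fast_slow(beh)
  for (s in unique(sp3$subj_idx)) {
    f <- sp3$speed == "fast" & sp3$subj_idx == s
    sl <- sp3$speed == "slow" & sp3$subj_idx == s
    expect_lt(mean(sp3$rt[which(f)]), mean(sp3$rt[which(sl)]))
  }
  expect_error(split_fast_slow(ev[1:3, ]), "fewer than 4")

  # the fast/slow design variant uses the recoded events
  des_ev <- generate_design(scaled_design_config(), seed = 4)
  full <- des_ev$trial_kind == "full"
  des_ev$rt <- NA_real_
  des_ev$accuracy <- NA_integer_
  des_ev$rt[full] <- runif(sum(full), 0.5, 3)
  des_ev$accuracy[full] <- 1L
  fs <- build_fir_design(split_fast_slow(des_ev), "fast_slow")
  expect_setequal(unique(fs$labels$event_type),
                  c("cue_f", "cue_n", "cue_h",
                    "stim_F_fast", "stim_F_slow",
                    "stim_H_fast", "stim_H_slow"))
})

test_that("ROI growing finds planted bumps and respects mask invariants", {
  bumps <- list(list(center = c(30, 30, 20), peak_z = 5, width_mm = 4),
                list(center = c(60, 50, 30), peak_z = -5, width_mm = 4))
  m <- generate_stat_map(bumps, dim = c(40, 40, 25), voxel_size_mm = 2,
                         noise_sd = 0.4, seed = 8)
  rois <- localize_rois(m, voxel_size_mm = 2)
  expect_equal(length(rois), 2)
  expect_setequal(vapply(rois, `[[`, "", "label"), c("face", "house"))
  for (r in rois) {
    d_mm <- sqrt(rowSums(sweep(r$voxels, 2, r$peak)^2)) * 2
    expect_true(all(d_mm <= 8))
    vals <- m[r$voxels]
    if (r$label == "face") expect_true(all(vals > 1.96))
    else expect_true(all(vals < -1.96))
  }
  face <- rois[[which(vapply(rois, `[[`, "", "label") == "face")]]
  expect_equal(face$peak, c(16, 16, 11), tolerance = 1)

  # subthreshold map yields an empty list, not an error
  quiet <- generate_stat_map(list(), dim = c(20, 20, 15), noise_sd = 0.3,
                             seed = 2)
  expect_equal(length(localize_rois(quiet, 2)), 0)

  # two well-separated bumps give disjoint masks
  two <- generate_stat_map(list(
    list(center = c(20, 20, 14), peak_z = 6, width_mm = 4),
    list(center = c(50, 20, 14), peak_z = 6, width_mm = 4)),
    dim = c(40, 25, 15), voxel_size_mm = 2, seed = 3)
  r2 <- localize_rois(two, 2)
  expect_equal(length(r2), 2)
  k1 <- apply(r2[[1]]$voxels, 1, paste, collapse = ",")
  k2 <- apply(r2[[2]]$voxels, 1, paste, collapse = ",")
  expect_equal(length(intersect(k1, k2)), 0)
})

test_that("prediction/surprise decomposition recovers generating weights", {
  e <- c(.8, .5, .2, .8, .5, .2)
  s <- c(.2, .5, .8, 0, 0, 0)
  y <- setNames(0.1 + 0.2 * e + 0.4 * s,
                c("fF", "nF", "hF", "fH", "nH", "hH"))
  fit <- fit_pc_decomposition(y)
  expect_equal(fit$baseline, 0.1, tolerance = 1e-8)
  expect_equal(fit$weight_prediction, 0.2, tolerance = 1e-8)
  expect_equal(fit$weight_surprise, 0.4, tolerance = 1e-8)
  expect_equal(fit$ratio, 2, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)

  y0 <- setNames(0.1 + 0.3 * e, names(y))
  expect_equal(fit_pc_decomposition(y0)$ratio, 0, tolerance = 1e-8)

  # noise robustness: median recovered ratio within 25% of truth
  set.seed(44)
  ratios <- replicate(100, {
    yn <- y + rnorm(6, 0, 0.1 * diff(range(y)))
    fit_pc_decomposition(setNames(yn, names(y)))$ratio
  })
  expect_lt(abs(median(ratios) - 2) / 2, 0.25)

  expect_error(fit_pc_decomposition(y, prob_face = c(f = .5, n = .5,
                                                     h = .5)),
               "unidentifiable")
  # house-preferring region mirrors the probabilities
  yh <- setNames(0.05 + 0.15 * (1 - e) + 0.3 * c(0, 0, 0, .8, .5, .2),
                 names(y))
  fh <- fit_pc_decomposition(yh, preferred = "house")
  expect_equal(fh$weight_prediction, 0.15, tolerance = 1e-8)
  expect_equal(fh$weight_surprise, 0.3, tolerance = 1e-8)
})
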