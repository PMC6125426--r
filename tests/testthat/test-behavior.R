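test_that("EWMA filter spares accurate data and removes fast guesses", {
  set.seed(1)
  clean_only <- data.frame(subj_idx = 1, rt = runif(100, 0.5, 2),
                           accuracy = 1)
  fl <- ewma_filter(clean_only)
  expect_equal(fl$removed_fraction, 0)
  expect_equal(unname(fl$cutoffs), 0)

  # 10% fast guesses at chance grafted onto accurate slow trials
  removed <- sapply(1:5, function(s) {
    set.seed(s)
    d <- rbind(data.frame(subj_idx = 1, rt = runif(540, 0.8, 2.5),
                          accuracy = rbinom(540, 1, 0.92)),
               data.frame(subj_idx = 1, rt = runif(60, 0.15, 0.3),
                          accuracy = rbinom(60, 1, 0.5)))
    ewma_filter(d)$removed_fraction
  })
  expect_lt(abs(mean(removed) - 0.10), 0.05)
  # cutoff falls between the guess range and the clean range
  set.seed(2)
  d <- rbind(data.frame(subj_idx = 1, rt = runif(540, 0.8, 2.5),
                        accuracy = rbinom(540, 1, 0.92)),
             data.frame(subj_idx = 1, rt = runif(60, 0.15, 0.3),
                        accuracy = rbinom(60, 1, 0.5)))
    fl2 <- ewma_filter(d)
  expect_gt(unname(fl2$cutoffs), 0.15)
  expect_lt(unname(fl2$cutoffs), 1.2)

  expect_error(ewma_filter(data.frame(subj_idx = 1, rt = 1:10 / 10,
                                      accuracy = 1)), "fewer than 20")
  expect_error(ewma_filter(data.frame(subj_idx = 1, rt = runif(30),
                                      accuracy = runif(30))), "binary")
})

test_that("EWMA removal is stable under trial duplication", {
  set.seed(3)
  d <- rbind(data.frame(subj_idx = 1, rt = runif(500, 0.8, 2.5),
                        accuracy = rbinom(500, 1, 0.92)),
             data.frame(subj_idx = 1, rt = runif(55, 0.15, 0.3),
                        accuracy = rbinom(55, 1, 0.5)))
  f1 <- ewma_filter(d)
  f2 <- ewma_filter(rbind(d, d))
  expect_lt(abs(f1$removed_fraction - f2$removed_fraction), 0.02)
})

test_that("condition summaries reproduce hand-computed values", {
  d <- data.frame(subj_idx = rep(1:2, each = 6),
                  cue = rep(c("80F", "50N", "80H"), 4),
                  stim = rep(rep(c("face", "house"), each = 3), 2),
                  rt = c(1, 1.2, 1.4, 2, 2.2, 2.4, 1.1, 1.3, 1.5, 2.1,
                         2.3, 2.5),
                  accuracy = c(1, 1, 0, 1, 0, 1, 1, 1, 1, 1, 1, 1))
  sm <- summarize_conditions(d)
  cell <- sm$cells[sm$cells$cue == "80F" & sm$cells$stim == "face", ]
  expect_equal(cell$accuracy, 1)
  expect_equal(cell$mean_rt_correct, mean(c(1, 1.1)))
  cell2 <- sm$cells[sm$cells$cue == "80H" & sm$cells$stim == "face", ]
  expect_equal(cell2$accuracy, 0.5)        # subject means (0, 1) averaged
  expect_equal(cell2$mean_rt_correct, 1.5) # only subject 2 correct
  expect_equal(sum(sm$cells$n), nrow(d))

  const <- data.frame(subj_idx = 1, cue = rep(c("80F", "50N", "80H"), 2),
                      stim = rep(c("face", "house"), each = 3),
                      rt = 1.3, accuracy = 1)
  smc <- summarize_conditions(const)
  expect_true(all(smc$cells$mean_rt_correct == 1.3))
  expect_true(all(smc$cells$accuracy == 1))
})

test_that("simulated valid-cue trials are faster and more accurate", {
  bd <- make_behavior(n_subjects = 6, seed = 21)
  sm <- summarize_conditions(bd$behavior)$cells
  acc <- function(cue, st) sm$accuracy[sm$cue == cue & sm$stim == st]
  rtc <- function(cue, st) sm$mean_rt_correct[sm$cue == cue & sm$stim == st]
  expect_gt(acc("80F", "face"), acc("80H", "face"))
  expect_gt(acc("80H", "house"), acc("80F", "house"))
  expect_lt(rtc("80F", "face"), rtc("80H", "face"))
})

test_that("repeated-measures ANOVA matches the car oracle exactly", {
  set.seed(6)
  d <- expand.grid(subj = 1:5, stim = c("face", "house"),
                   cue = c("80H", "50N", "80F"))
  d$y <- rnorm(nrow(d)) + 0.4 * (d$stim == "face") +
    0.2 * as.numeric(d$cue)
  res <- rm_anova_gg(d, "y", "subj", c("stim", "cue"))

  cells <- expand.grid(stim = c("face", "house"),
                       cue = c("80H", "50N", "80F"))
  Y <- sapply(seq_len(nrow(cells)), function(i) {
    sel <- d$stim == cells$stim[i] & d$cue == cells$cue[i]
    d$y[sel][order(d$subj[sel])]
  })
  av <- car::Anova(lm(Y ~ 1),
                   idata = data.frame(stim = factor(cells$stim),
                                      cue = factor(cells$cue)),
                   idesign = ~ stim * cue, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  expect_equal(res$F, unname(ut[c("stim", "cue", "stim:cue"), "F value"]),
               tolerance = 1e-8)
  expect_equal(res$p, unname(ut[c("stim", "cue", "stim:cue"), "Pr(>F)"]),
               tolerance = 1e-8)
  pa <- s$pval.adjustments
  expect_equal(res$epsilon[2:3], unname(pa[c("cue", "stim:cue"), "GG eps"]),
               tolerance = 1e-8)
  expect_equal(res$p_gg[2:3], unname(pa[c("cue", "stim:cue"), "Pr(>F[GG])"]),
               tolerance = 1e-8)

  # a 2-level factor is trivially spherical
  expect_equal(res$epsilon[1], 1)
  expect_equal(res$df1_gg[1], res$df1[1])
  expect_error(rm_anova_gg(d[d$subj != 1 | d$stim != "face", ], "y", "subj",
                           c("stim", "cue")), "missing cells")
})

test_that("epsilon approaches 1 under compound symmetry", {
  set.seed(11)
  n <- 50
  subj_eff <- rnorm(n, 0, 1)
  d <- expand.grid(subj = 1:n, cond = paste0("c", 1:3))
  d$y <- subj_eff[d$subj] + rnorm(nrow(d), 0, 0.8)
  res <- rm_anova_gg(d, "y", "subj", "cond")
  expect_lt(abs(res$epsilon - 1), 0.05)
})

test_that("GG-corrected type-I error stays nominal under nonsphericity", {
  set.seed(99)
  n <- 19; reps <- 1000
  # heterogeneous covariance: strongly unequal variances violate sphericity
  sds <- c(0.3, 1, 2.2)
  p_gg <- p_raw <- numeric(reps)
  for (r in seq_len(reps)) {
    subj_eff <- rnorm(n)
    y <- subj_eff + sweep(matrix(rnorm(n * 3), n, 3), 2, sds, `*`)
    d <- data.frame(subj = rep(1:n, 3),
                    cond = rep(paste0("c", 1:3), each = n),
                    y = as.vector(y))
    res <- rm_anova_gg(d, "y", "subj", "cond")
    p_gg[r] <- res$p_gg
    p_raw[r] <- res$p
  }
  rate_gg <- mean(p_gg < 0.05)
  rate_raw <- mean(p_raw < 0.05)
  expect_lt(abs(rate_gg - 0.05), 0.015)
  expect_gt(rate_raw, rate_gg)  # uncorrected dfs inflate the error rate
})

test_that("Sidak adjustment follows the closed form and is monotone", {
  expect_equal(sidak_adjust(0, m = 4), 0)
  expect_equal(sidak_adjust(0.05, m = 1), 0.05)
  expect_equal(sidak_adjust(0.02, m = 3), 1 - 0.98^3)
  p <- c(0.001, 0.02, 0.5, 0.9)
  adj <- sidak_adjust(p, m = 4)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(sidak_adjust(numeric(0), m = 0), "m")

  set.seed(2)
  tab <- data.frame(a = rnorm(10), b = rnorm(10, 0.5), c = rnorm(10, 1))
  out <- sidak_pairwise(tab, list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(out$p_adj, 1 - (1 - out$p)^3)
})
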