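#' Fit a hierarchical cue-bias drift-diffusion model
#'
#' The package's central fitting function. Builds the requested model
#' variant (starting-point bias, drift-rate bias, or both; see
#' [model_spec()]), samples its posterior by adaptive
#' Metropolis-within-Gibbs ([sample_posterior()]) and computes the DIC
#' decomposition ([compute_dic()]). The face response is coded to the upper
#' boundary and the starting point is relative (0 = house boundary,
#' 1 = face boundary) throughout.
#'
#' @param data Behavioral table with columns `subj_idx`, `cue`
#'   (`80F`/`50N`/`80H`), `stim` (`face`/`house`), `response`
#'   (`face`/`house`), `rt` (seconds). Typically the output of
#'   [simulate_behavior()] after [ewma_filter()].
#' @param model `"PBM"`, `"DBM"` or `"MSM"`, or a [model_spec()].
#' @param priors See [default_priors()].
#' @param chains,draws,burnin,thin,seed Sampler settings, passed to
#'   [sample_posterior()].
#' @param ... Further arguments to [build_model()] (e.g. `err`, `penalty`).
#' @return An object of class `"hddm"` with components `samples`
#'   (`"hddm_samples"`), `dic` (`"fit_result"`), `model` (`"hddm_model"`)
#'   and the matched call. Methods: `print`, `summary`, `coef`, `simulate`,
#'   `plot`.
#' @seealso [posterior_probability()], [posterior_predict()],
#'   [compare_models()]
#' @export
fit_hddm <- function(data, model = c("MSM", "PBM", "DBM"),
                     priors = default_priors(), chains = 3, draws = 2000,
                     burnin = 1000, thin = 1L, seed = 1L, ...) {
  if (is.character(model)) model <- model_spec(match.arg(model))
  mod <- build_model(data, spec = model, priors = priors, ...)
  samples <- sample_posterior(mod, chains = chains, draws = draws,
                              burnin = burnin, seed = seed, thin = thin)
  dic <- compute_dic(samples, mod)
  structure(list(model_name = mod$spec$name, samples = samples, dic = dic,
                 model = mod, call = match.call()),
            class = "hddm")
}

#' @export
print.hddm <- function(x, ...) {
  cat(sprintf("Hierarchical %s drift-diffusion fit\n", x$model_name))
  cat(sprintf("  %d subjects, %d trials; %d chains x %d draws\n",
              x$model$n_subjects, x$model$n_trials,
              length(x$samples$chains), nrow(x$samples$chains[[1]])))
  print(x$dic)
  gm <- coef(x)
  cat("Group means:\n")
  print(round(gm, 3))
  invisible(x)
}

#' @export
coef.hddm <- function(object, ...) {
  pooled <- do.call(rbind, object$samples$chains)
  mu <- paste0("mu_", object$samples$types)
  stats::setNames(colMeans(pooled[, mu, drop = FALSE]), mu)
}

#' @export
summary.hddm <- function(object, level = 0.95, ...) {
  pooled <- do.call(rbind, object$samples$chains)
  alpha <- (1 - level) / 2
  grp <- c(paste0("mu_", object$samples$types),
           paste0("sigma_", object$samples$types), "sv", "sz", "st")
  tab <- t(apply(pooled[, grp, drop = FALSE], 2, function(d)
    c(mean = mean(d), sd = stats::sd(d),
      lower = unname(stats::quantile(d, alpha)),
      upper = unname(stats::quantile(d, 1 - alpha)))))
  tab <- cbind(tab, rhat = object$samples$rhat[grp])
  out <- list(model = object$model_name, group = tab, dic = object$dic,
              level = level)
  class(out) <- "summary.hddm"
  out
}

#' @export
print.summary.hddm <- function(x, ...) {
  cat(sprintf("Hierarchical %s fit — group-level posterior (%.0f%% interval)\n",
              x$model, 100 * x$level))
  print(round(x$group, 3))
  print(x$dic)
  invisible(x)
}

#' Posterior predictive simulation method
#'
#' `simulate()` on a fitted `"hddm"` object draws `nsim` posterior
#' predictive datasets via [posterior_predict()].
#'
#' @param object An `"hddm"` fit.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param ... Passed to [posterior_predict()].
#' @return See [posterior_predict()].
#' @export
simulate.hddm <- function(object, nsim = 1, seed = 1L, ...) {
  posterior_predict(object, n_datasets = nsim, seed = seed, ...)
}

#' Trace and density plots for a fitted model
#'
#' @param x An `"hddm"` fit.
#' @param pars Parameters to plot (default: group means).
#' @param ... Unused.
#' @export
plot.hddm <- function(x, pars = NULL, ...) {
  if (is.null(pars)) pars <- paste0("mu_", x$samples$types)
  pars <- pars[pars %in% x$samples$param_names]
  np <- length(pars)
  old <- graphics::par(mfrow = c(min(np, 4), 2), mar = c(2.5, 2.5, 1.5, 0.5),
                       mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(old))
  for (p in utils::head(pars, 4)) {
    draws <- lapply(x$samples$chains, function(m) m[, p])
    graphics::plot(draws[[1]], type = "l", col = 1, ylab = p, xlab = "draw",
                   ylim = range(unlist(draws)), main = p)
    if (length(draws) > 1)
      for (i in 2:length(draws))
        graphics::lines(draws[[i]], col = i)
    graphics::plot(stats::density(unlist(draws)), main = "", xlab = p)
  }
  invisible(x)
}
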