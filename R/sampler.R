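#' Sample the posterior of a hierarchical cue-bias model
#'
#' Adaptive Metropolis-within-Gibbs sampler. Each subject-level parameter
#' and each group hyperparameter is updated with a Gaussian random-walk
#' proposal whose scale is tuned during burn-in towards an acceptance rate
#' of 0.44 and frozen afterwards. Per-cell log-likelihoods are cached so a
#' parameter update only re-evaluates the condition cells it touches; the
#' group-level variability parameters (`sv`, `sz`, `st`) each require a full
#' likelihood pass and are updated round-robin, one per sweep. The deviance (-2 log-likelihood at the subject-level
#' parameters) is recorded at every retained draw.
#'
#' @param model An [build_model()] object.
#' @param chains Number of chains (>= 2 recommended for split-R-hat
#'   diagnostics; a single chain triggers a warning).
#' @param draws Retained draws per chain after burn-in.
#' @param burnin Burn-in sweeps per chain (adaptation window).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param progress Print progress every 500 sweeps.
#' @return An object of class `"hddm_samples"`: per-chain draw matrices,
#'   per-chain deviance vectors, parameter names and split-R-hat values.
#' @export
sample_posterior <- function(model, chains = 3, draws = 2000, burnin = 1000,
                             seed = 1L, thin = 1L, progress = FALSE) {
  stopifnot(inherits(model, "hddm_model"))
  if (chains < 2)
    warning("fewer than 2 chains: R-hat diagnostics unavailable")
  if (draws < 1 || burnin < 0) stop("invalid draws/burnin", call. = FALSE)

  out <- vector("list", chains)
  dev <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- run_chain(model, draws = draws, burnin = burnin,
                     seed = as.integer(seed) + ch - 1L, thin = thin,
                     progress = progress)
    out[[ch]] <- res$draws
    dev[[ch]] <- res$deviance
  }
  param_names <- colnames(out[[1]])
  rh <- if (chains >= 2) split_rhat(out) else
    stats::setNames(rep(NA_real_, length(param_names)), param_names)
  warn <- NULL
  if (chains >= 2 && any(rh > 1.05, na.rm = TRUE)) {
    bad <- names(rh)[which(rh > 1.05)]
    warn <- sprintf("R-hat > 1.05 for %d parameter(s): %s", length(bad),
                    paste(utils::head(bad, 5), collapse = ", "))
    warning(warn)
  }
  structure(list(chains = out, deviance = dev, param_names = param_names,
                 types = model$spec$subject_types, subjects = model$subjects,
                 model_name = model$spec$name, rhat = rh,
                 convergence_warning = warn,
                 config = list(chains = chains, draws = draws,
                               burnin = burnin, seed = seed, thin = thin)),
            class = "hddm_samples")
}

#' @export
print.hddm_samples <- function(x, ...) {
  cat(sprintf("Posterior samples (%s): %d chains x %d draws, %d parameters\n",
              x$model_name, length(x$chains), nrow(x$chains[[1]]),
              length(x$param_names)))
  if (!is.null(x$convergence_warning)) cat("  ", x$convergence_warning, "\n")
  invisible(x)
}

# split-half R-hat per parameter across chains
split_rhat <- function(chain_mats) {
  n <- nrow(chain_mats[[1]])
  half <- n %/% 2
  pieces <- list()
  for (m in chain_mats) {
    pieces <- c(pieces, list(m[seq_len(half), , drop = FALSE],
                             m[(half + 1):(2 * half), , drop = FALSE]))
  }
  nn <- half
  means <- sapply(pieces, colMeans)
  vars <- sapply(pieces, function(p) apply(p, 2, stats::var))
  B <- nn * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  vhat <- (nn - 1) / nn * W + B / nn
  rh <- sqrt(vhat / W)
  rh[W <= 0] <- 1
  stats::setNames(rh, colnames(chain_mats[[1]]))
}

run_chain <- function(model, draws, burnin, seed, thin = 1L,
                      progress = FALSE) {
  set.seed(seed)
  spec <- model$spec
  types <- spec$subject_types
  cells <- spec$cells
  S <- model$n_subjects
  P <- length(types)
  priors <- model$priors
  err <- model$err; pen <- model$penalty

  # fast lookup structures
  zi <- match(vapply(spec$cell_map, `[[`, "", "z"), types)
  vi <- match(vapply(spec$cell_map, `[[`, "", "v"), types)
  names(zi) <- names(vi) <- cells
  ia <- match("a", types); itr <- match("tr", types)
  aff <- lapply(spec$affected, function(cl) match(cl, cells))
  z_cols <- which(vapply(types, function(p) type_class(p) == "z", logical(1)))
  rts <- lapply(model$data_cells, function(sc) lapply(sc, `[[`, "rt"))
  ups <- lapply(model$data_cells, function(sc) lapply(sc, `[[`, "up"))
  all_rt <- unlist(rts, use.names = FALSE)
  min_rt <- min(all_rt)

  cls <- vapply(types, type_class, "")
  pm <- priors$group_mean
  dom <- priors$subject_domain

  # --- initialization (mildly dispersed across chains via the RNG) ---
  mu <- vapply(types, function(p) {
    base <- switch(cls[[p]],
                   a = 1.5,
                   tr = max(0.05, 0.5 * min_rt),
                   z = 0.55,
                   v = if (endsWith(p, "H")) -0.8 else 0.8)
    base * (1 + 0.05 * stats::rnorm(1))
  }, 0)
  sigma <- stats::setNames(rep(0.1, P), types)
  varp <- c(sv = abs(0.3 + 0.05 * stats::rnorm(1)),
            sz = 0.05, st = min(0.1, max(0.02, 0.3 * min_rt)))
  subj <- matrix(rep(mu, each = S), nrow = S,
                 dimnames = list(NULL, types))
  subj <- subj * (1 + 0.02 * matrix(stats::rnorm(S * P), S, P))
  # keep inside domains
  for (p in seq_len(P)) {
    d <- dom[[cls[p]]]
    subj[, p] <- pmin(pmax(subj[, p], d[1] + 1e-3),
                      if (is.finite(d[2])) d[2] - 1e-3 else Inf)
  }

  cell_ll <- function(s, ci, row, vp) {
    ddm_loglik_cpp(rts[[s]][[ci]], ups[[s]][[ci]], row[ia], row[zi[ci]],
                   row[vi[ci]], row[itr], vp[1L], vp[2L], vp[3L], err, pen)
  }
  ok_row <- function(row, sz, st) {
    z <- row[z_cols]
    all(z - sz / 2 > 1e-3) && all(z + sz / 2 < 1 - 1e-3) &&
      row[itr] - st / 2 >= 0
  }

  llmat <- matrix(0, S, length(cells))
  for (s in seq_len(S)) for (ci in seq_along(cells))
    llmat[s, ci] <- cell_ll(s, ci, subj[s, ], varp)

  # proposal scales
  psd_subj <- matrix(rep(c(a = 0.1, tr = 0.03, z = 0.03,
                           v = 0.15)[cls], each = S), S, P)
  psd_mu <- c(a = 0.1, tr = 0.03, z = 0.03, v = 0.15)[cls]
  psd_sigma <- rep(0.05, P)
  psd_var <- c(sv = 0.15, sz = 0.03, st = 0.03)
  acc_subj <- matrix(0, S, P); try_subj <- matrix(0, S, P)
  acc_mu <- try_mu <- acc_sigma <- try_sigma <- rep(0, P)
  acc_var <- try_var <- c(sv = 0, sz = 0, st = 0)
  trans_types <- unname(which(cls %in% c("z", "v")))
  psd_trans <- rep(0, P)
  psd_trans[trans_types] <- unname(c(z = 0.03, v = 0.12)[cls[trans_types]])
  acc_trans <- try_trans <- rep(0, P)
  tune_every <- 25L

  n_sweeps <- burnin + draws * thin
  keep_names <- c(paste0("mu_", types), paste0("sigma_", types),
                  "sv", "sz", "st", model$subj_names)
  kept <- matrix(NA_real_, draws, length(keep_names),
                 dimnames = list(NULL, keep_names))
  dev_kept <- numeric(draws)
  kidx <- 0L

  for (it in seq_len(n_sweeps)) {
    ## subject-level updates
    for (s in seq_len(S)) {
      row <- subj[s, ]
      for (p in seq_len(P)) {
        cur <- row[p]
        prop <- cur + psd_subj[s, p] * stats::rnorm(1)
        try_subj[s, p] <- try_subj[s, p] + 1
        d <- dom[[cls[p]]]
        if (prop <= d[1] || prop >= d[2]) next
        newrow <- row; newrow[p] <- prop
        if (p %in% z_cols || p == itr) {
          if (!ok_row(newrow, varp[2L], varp[3L])) next
        }
        lpd <- stats::dnorm(prop, mu[p], sigma[p], log = TRUE) -
          stats::dnorm(cur, mu[p], sigma[p], log = TRUE)
        ci_aff <- aff[[p]]
        newll <- vapply(ci_aff, function(ci) cell_ll(s, ci, newrow, varp), 0)
        if (log(stats::runif(1)) < lpd + sum(newll) - sum(llmat[s, ci_aff])) {
          row <- newrow
          llmat[s, ci_aff] <- newll
          acc_subj[s, p] <- acc_subj[s, p] + 1
        }
      }
      subj[s, ] <- row
    }

    ## group means and SDs (no likelihood term)
    for (p in seq_len(P)) {
      pr <- pm[[cls[p]]]
      d <- dom[[cls[p]]]
      # mu
      cur <- mu[p]; prop <- cur + psd_mu[p] * stats::rnorm(1)
      try_mu[p] <- try_mu[p] + 1
      lp0 <- log_dtnorm(cur, pr$mean, pr$sd, pr$lower, pr$upper) +
        log_dtnorm_sum(subj[, p], cur, sigma[p], d[1], d[2])
      lp1 <- log_dtnorm(prop, pr$mean, pr$sd, pr$lower, pr$upper) +
        log_dtnorm_sum(subj[, p], prop, sigma[p], d[1], d[2])
      if (is.finite(lp1) && log(stats::runif(1)) < lp1 - lp0) {
        mu[p] <- prop; acc_mu[p] <- acc_mu[p] + 1
      }
      # sigma
      cur <- sigma[p]; prop <- cur + psd_sigma[p] * stats::rnorm(1)
      try_sigma[p] <- try_sigma[p] + 1
      if (prop > 1e-4) {
        lp0 <- log_dhalfnorm(cur, priors$group_sd$scale) +
          log_dtnorm_sum(subj[, p], mu[p], cur, d[1], d[2])
        lp1 <- log_dhalfnorm(prop, priors$group_sd$scale) +
          log_dtnorm_sum(subj[, p], mu[p], prop, d[1], d[2])
        if (is.finite(lp1) && log(stats::runif(1)) < lp1 - lp0) {
          sigma[p] <- prop; acc_sigma[p] <- acc_sigma[p] + 1
        }
      }
    }

    ## group translation moves: shift a group mean and every subject's value
    ## jointly, so the group location can move even when the group SD is
    ## small (the hierarchical funnel); z and v families only - their cell
    ## subsets keep the likelihood pass cheap
    for (p in trans_types) {
      delta <- psd_trans[p] * stats::rnorm(1)
      try_trans[p] <- try_trans[p] + 1
      pr <- pm[[cls[p]]]
      d <- dom[[cls[p]]]
      mu_new <- mu[p] + delta
      th_new <- subj[, p] + delta
      if (mu_new <= pr$lower || mu_new >= pr$upper ||
          any(th_new <= d[1]) || any(th_new >= d[2])) next
      if (cls[p] == "z" &&
          (any(th_new - varp[2L] / 2 <= 1e-3) ||
           any(th_new + varp[2L] / 2 >= 1 - 1e-3))) next
      lp <- log_dtnorm(mu_new, pr$mean, pr$sd, pr$lower, pr$upper) -
        log_dtnorm(mu[p], pr$mean, pr$sd, pr$lower, pr$upper) +
        log_dtnorm_sum(th_new, mu_new, sigma[p], d[1], d[2]) -
        log_dtnorm_sum(subj[, p], mu[p], sigma[p], d[1], d[2])
      ci_aff <- aff[[p]]
      newll <- matrix(0, S, length(ci_aff))
      for (s in seq_len(S)) {
        row <- subj[s, ]; row[p] <- th_new[s]
        for (j in seq_along(ci_aff))
          newll[s, j] <- cell_ll(s, ci_aff[j], row, varp)
      }
      if (is.finite(lp) &&
          log(stats::runif(1)) < lp + sum(newll) -
            sum(llmat[, ci_aff])) {
        mu[p] <- mu_new
        subj[, p] <- th_new
        llmat[, ci_aff] <- newll
        acc_trans[p] <- acc_trans[p] + 1
      }
    }

    ## group variability parameters (full likelihood): round-robin, one per
    ## sweep, since each proposal costs a complete data pass
    for (vn in c("sv", "sz", "st")[1L + (it %% 3L)]) {
      cur <- varp[[vn]]
      prop <- cur + psd_var[[vn]] * stats::rnorm(1)
      try_var[[vn]] <- try_var[[vn]] + 1
      lp_prop <- switch(vn,
                        sv = log_dhalfnorm(prop, priors$sv$scale),
                        sz = log_dunif0(prop, priors$sz$upper),
                        st = log_dunif0(prop, priors$st$upper))
      if (!is.finite(lp_prop)) next
      lp_cur <- switch(vn,
                       sv = log_dhalfnorm(cur, priors$sv$scale),
                       sz = log_dunif0(cur, priors$sz$upper),
                       st = log_dunif0(cur, priors$st$upper))
      newvarp <- varp; newvarp[[vn]] <- prop
      if (vn %in% c("sz", "st")) {
        bad <- FALSE
        for (s in seq_len(S))
          if (!ok_row(subj[s, ], newvarp[2L], newvarp[3L])) { bad <- TRUE; break }
        if (bad) next
      }
      newll <- matrix(0, S, length(cells))
      for (s in seq_len(S)) for (ci in seq_along(cells))
        newll[s, ci] <- cell_ll(s, ci, subj[s, ], newvarp)
      if (log(stats::runif(1)) < lp_prop - lp_cur + sum(newll) - sum(llmat)) {
        varp <- newvarp
        llmat <- newll
        acc_var[[vn]] <- acc_var[[vn]] + 1
      }
    }

    ## adaptation during burn-in
    if (it <= burnin && it %% tune_every == 0L) {
      adapt <- function(sd, acc, tries) {
        rate <- ifelse(tries > 0, acc / tries, 0.44)
        pmin(pmax(sd * exp(1.2 * (rate - 0.44)), 1e-4), 5)
      }
      psd_subj <- adapt(psd_subj, acc_subj, try_subj)
      psd_mu <- adapt(psd_mu, acc_mu, try_mu)
      psd_sigma <- adapt(psd_sigma, acc_sigma, try_sigma)
      psd_var <- adapt(psd_var, acc_var, try_var)
      psd_trans[trans_types] <- adapt(psd_trans[trans_types],
                                      acc_trans[trans_types],
                                      try_trans[trans_types])
      acc_subj[] <- try_subj[] <- 0
      acc_mu[] <- try_mu[] <- acc_sigma[] <- try_sigma[] <- 0
      acc_var[] <- try_var[] <- 0
      acc_trans[] <- try_trans[] <- 0
    }

    if (it > burnin && (it - burnin) %% thin == 0L) {
      kidx <- kidx + 1L
      kept[kidx, ] <- c(mu, sigma, varp, as.vector(t(subj)))
      dev_kept[kidx] <- -2 * sum(llmat)
    }
    if (progress && it %% 500L == 0L)
      message(sprintf("  sweep %d / %d", it, n_sweeps))
  }
  list(draws = kept, deviance = dev_kept)
}

# Generic random-walk Metropolis on a log-density; used for small oracle
# checks of the sampling machinery against conjugate posteriors.
rw_metropolis <- function(logpost, init, n, proposal_sd, seed = 1L,
                          burnin = 0L) {
  set.seed(seed)
  d <- length(init)
  out <- matrix(NA_real_, n, d)
  cur <- init
  lp <- logpost(cur)
  for (it in seq_len(burnin + n)) {
    prop <- cur + proposal_sd * stats::rnorm(d)
    lpp <- logpost(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      cur <- prop; lp <- lpp
    }
    if (it > burnin) out[it - burnin, ] <- cur
  }
  out
}
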