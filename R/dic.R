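#' Construct a DIC fit result
#'
#' Packages a deviance decomposition into a fit-result object in which the
#' identity `DIC = Deviance + pD` holds exactly: the posterior-mean deviance
#' measures misfit and pD the effective number of parameters (Spiegelhalter
#' plug-in convention).
#'
#' @param deviance_bar Posterior mean deviance (D-bar).
#' @param pd Effective number of parameters.
#' @param model Model label.
#' @param checksum Optional data signature used by [compare_models()].
#' @param convergence Optional convergence summary.
#' @return An object of class `"fit_result"`.
#' @examples
#' fit_result(26593.57, 130.30, "PBM")$dic
#' @export
fit_result <- function(deviance_bar, pd, model = "", checksum = NULL,
                       convergence = NULL) {
  stopifnot(is.finite(deviance_bar), is.finite(pd))
  if (pd < 0)
    warning("negative pD: the plug-in deviance exceeds the posterior mean ",
            "deviance; the fit may be poorly identified")
  structure(list(deviance_bar = deviance_bar, pd = pd,
                 dic = deviance_bar + pd, model = model,
                 checksum = checksum, convergence = convergence),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s: DIC = %.2f (Deviance = %.2f, pD = %.2f)\n",
              if (nzchar(x$model)) x$model else "fit",
              x$dic, x$deviance_bar, x$pd))
  invisible(x)
}

#' Deviance Information Criterion of a posterior sample
#'
#' Computes D-bar as the mean over retained draws of -2 log-likelihood at
#' the subject-level parameters, the plug-in deviance D(theta-bar) at the
#' posterior mean of the subject-level parameters (and of the group
#' variability parameters sv, sz, st, which enter the likelihood), and
#' `pD = D-bar - D(theta-bar)`, `DIC = D-bar + pD`. Lower DIC indicates a
#' better fit after the complexity penalty.
#'
#' @param samples An [sample_posterior()] result.
#' @param model The [build_model()] object the samples came from.
#' @return A [fit_result()].
#' @export
compute_dic <- function(samples, model) {
  stopifnot(inherits(samples, "hddm_samples"), inherits(model, "hddm_model"))
  ndraw <- sum(vapply(samples$deviance, length, 0L))
  if (ndraw < 100) stop("too few draws for DIC (< 100)", call. = FALSE)
  dbar <- mean(unlist(samples$deviance))
  pooled <- do.call(rbind, samples$chains)
  means <- colMeans(pooled)
  types <- samples$types
  S <- length(samples$subjects)
  subj <- matrix(means[model$subj_names], nrow = S, byrow = TRUE,
                 dimnames = list(NULL, types))
  varp <- c(sv = means[["sv"]], sz = means[["sz"]], st = means[["st"]])
  dhat <- -2 * model$log_likelihood(subj, varp)
  fit_result(dbar, dbar - dhat, model = samples$model_name,
             checksum = model$checksum,
             convergence = list(rhat_max = suppressWarnings(
               max(samples$rhat, na.rm = TRUE))))
}

#' Rank models by DIC
#'
#' Orders fits by ascending DIC and flags pairwise differences of 10 or
#' more as significant (the conventional decision threshold for comparing
#' hierarchical model fits on the same data).
#'
#' @param fits A list of [fit_result()] objects (or `"hddm"` fits), all fit
#'   to the same dataset.
#' @return A list with the ranking table (`ranking`), the pairwise DIC
#'   difference matrix (`delta`), and a logical significance matrix
#'   (`significant`, `|delta| >= 10`).
#' @export
compare_models <- function(fits) {
  fits <- lapply(fits, function(f) if (inherits(f, "hddm")) f$dic else f)
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "fit_result")))
  sums <- lapply(fits, `[[`, "checksum")
  have <- !vapply(sums, is.null, TRUE)
  if (sum(have) >= 2) {
    keys <- vapply(sums[have], function(s) paste(unlist(s), collapse = "|"), "")
    if (length(unique(keys)) > 1)
      stop("fits were computed on different datasets", call. = FALSE)
  }
  nm <- vapply(seq_along(fits), function(i) {
    m <- fits[[i]]$model
    if (nzchar(m)) m else paste0("model", i)
  }, "")
  dic <- vapply(fits, `[[`, 0, "dic")
  ord <- order(dic)
  ranking <- data.frame(model = nm[ord], dic = dic[ord],
                        deviance = vapply(fits, `[[`, 0, "deviance_bar")[ord],
                        pd = vapply(fits, `[[`, 0, "pd")[ord],
                        delta_dic = dic[ord] - min(dic),
                        row.names = NULL)
  delta <- outer(dic, dic, `-`)
  dimnames(delta) <- list(nm, nm)
  list(ranking = ranking, winner = nm[ord[1]], delta = delta,
       significant = abs(delta) >= 10)
}
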