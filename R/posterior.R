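#' Directional posterior hypothesis test
#'
#' Fraction of paired posterior draws satisfying an inequality between two
#' parameters, e.g. `P(z_h < z_n)`. Draws are paired by draw index within
#' chain (never resampled independently), so posterior correlation between
#' the parameters is respected. When `absolute = TRUE` the comparison is on
#' absolute values, the convention used for drift rates so that larger
#' numbers always mean faster evidence accumulation regardless of the sign
#' coding of the house boundary.
#'
#' @param samples An `"hddm_samples"` or `"hddm"` object.
#' @param a,b Parameter names. Bare subject-type names (e.g. `"z_h"`) are
#'   resolved to the group mean (`"mu_z_h"`).
#' @param direction `"<"` or `">"` (strict inequalities).
#' @param absolute Compare `|a|` and `|b|` instead of raw values.
#' @return A probability in \[0, 1\].
#' @examples
#' \dontrun{p <- posterior_probability(fit, "z_h", "z_n", "<")}
#' @export
posterior_probability <- function(samples, a, b, direction = c("<", ">"),
                                  absolute = FALSE) {
  direction <- match.arg(direction)
  if (inherits(samples, "hddm")) samples <- samples$samples
  stopifnot(inherits(samples, "hddm_samples"))
  pooled <- do.call(rbind, samples$chains)
  da <- pooled[, resolve_param(a, colnames(pooled))]
  db <- pooled[, resolve_param(b, colnames(pooled))]
  if (length(da) != length(db)) stop("mismatched draw counts", call. = FALSE)
  if (absolute) { da <- abs(da); db <- abs(db) }
  if (direction == "<") mean(da < db) else mean(da > db)
}

resolve_param <- function(p, names) {
  if (p %in% names) return(p)
  mu <- paste0("mu_", p)
  if (mu %in% names) return(mu)
  stop(sprintf("unknown parameter '%s'", p), call. = FALSE)
}

#' Posterior predictive datasets
#'
#' Simulates behavioral datasets from the joint posterior: for each dataset
#' and each subject, one retained draw of that subject's parameters (and of
#' the group variability parameters from the same draw) is selected at
#' random, and the subject's trials are forward-simulated with the same
#' per-condition trial counts as the fitted (or supplied) design. Returns
#' per-dataset condition summaries (mean accuracy and mean correct RT per
#' cue x stimulus cell) and pooled RT quantiles for correct and error
#' responses, the surfaces used for graphical posterior predictive checks.
#'
#' @param fit An `"hddm"` fit (or list with elements `samples` and `model`).
#' @param design Optional event table (see [generate_design()]); per-subject
#'   per-cell trial counts are taken from its full trials. Default: the
#'   counts of the fitted data.
#' @param n_datasets Number of simulated datasets (default 100).
#' @param seed Integer seed.
#' @param dt Simulator step; the coarser default (1e-3 s) is intended for
#'   bulk posterior predictive runs.
#' @param deadline Response deadline (s).
#' @param keep_datasets Return the trial-level datasets as well.
#' @param quantile_probs RT quantiles reported for correct/error pools.
#' @return A list with `summaries` (data.frame: dataset, cue, stim, n,
#'   accuracy, mean_rt_correct), `quantiles` (data.frame: dataset, outcome,
#'   prob, rt), and optionally `datasets`.
#' @export
posterior_predict <- function(fit, design = NULL, n_datasets = 100,
                              seed = 1L, dt = 1e-3, deadline = 6,
                              keep_datasets = FALSE,
                              quantile_probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (n_datasets < 1) stop("'n_datasets' must be >= 1", call. = FALSE)
  samples <- fit$samples
  model <- fit$model
  stopifnot(inherits(samples, "hddm_samples"), inherits(model, "hddm_model"))
  spec <- model$spec
  cells <- spec$cells
  subjects <- model$subjects
  S <- length(subjects)

  counts <- cell_counts_for_predict(model, design, subjects, cells)

  pooled <- do.call(rbind, samples$chains)
  ndraw <- nrow(pooled)
  set.seed(as.integer(seed))

  summaries <- vector("list", n_datasets)
  qlist <- vector("list", n_datasets)
  datasets <- if (keep_datasets) vector("list", n_datasets) else NULL
  sim_seeds <- sample.int(.Machine$integer.max - 1L,
                          n_datasets * S * length(cells))
  k <- 0L
  for (d in seq_len(n_datasets)) {
    rows <- vector("list", S * length(cells))
    r <- 0L
    for (si in seq_len(S)) {
      ix <- sample.int(ndraw, 1)
      draw <- pooled[ix, ]
      for (ci in seq_along(cells)) {
        k <- k + 1L; r <- r + 1L
        n_cell <- counts[si, ci]
        if (n_cell == 0) next
        cl <- cells[ci]
        m <- spec$cell_map[[cl]]
        p <- ddm_params(a = draw[[paste0("a[", subjects[si], "]")]],
                        z = draw[[paste0(m[["z"]], "[", subjects[si], "]")]],
                        v = draw[[paste0(m[["v"]], "[", subjects[si], "]")]],
                        tr = draw[[paste0("tr[", subjects[si], "]")]],
                        sv = draw[["sv"]], sz = min(draw[["sz"]], 1.9 *
                          min(draw[[paste0(m[["z"]], "[", subjects[si], "]")]],
                              1 - draw[[paste0(m[["z"]], "[", subjects[si], "]")]])),
                        st = min(draw[["st"]],
                                 2 * draw[[paste0("tr[", subjects[si], "]")]]))
        tr_out <- simulate_ddm(p, n_cell, deadline = deadline,
                               seed = sim_seeds[k], dt = dt)
        stim <- substr(cl, 2, 2)
        resp <- ifelse(tr_out$choice == "upper", "face",
                       ifelse(tr_out$choice == "lower", "house",
                              "no_response"))
        rows[[r]] <- data.frame(
          subj_idx = subjects[si],
          cue = unname(c(f = "80F", n = "50N", h = "80H")[substr(cl, 1, 1)]),
          stim = unname(c(F = "face", H = "house")[stim]),
          response = resp, rt = tr_out$rt,
          accuracy = as.integer(resp == c(F = "face", H = "house")[stim]),
          stringsAsFactors = FALSE)
      }
    }
    ds <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    row.names(ds) <- NULL
    resp_ok <- ds$response != "no_response"
    cell_key <- interaction(ds$cue, ds$stim, drop = FALSE)
    sm <- do.call(rbind, lapply(split(ds[resp_ok, ], droplevels(
      cell_key[resp_ok])), function(g) {
        data.frame(cue = g$cue[1], stim = g$stim[1], n = nrow(g),
                   accuracy = mean(g$accuracy),
                   mean_rt_correct = mean(g$rt[g$accuracy == 1]),
                   stringsAsFactors = FALSE)
      }))
    sm$dataset <- d
    summaries[[d]] <- sm
    qs <- lapply(c(correct = 1, error = 0), function(acc) {
      rt <- ds$rt[resp_ok & ds$accuracy == acc]
      if (length(rt) < 2) return(NULL)
      data.frame(dataset = d, outcome = if (acc == 1) "correct" else "error",
                 prob = quantile_probs,
                 rt = as.numeric(stats::quantile(rt, quantile_probs)),
                 stringsAsFactors = FALSE)
    })
    qlist[[d]] <- do.call(rbind, qs)
    if (keep_datasets) datasets[[d]] <- ds
  }
  out <- list(summaries = do.call(rbind, summaries),
              quantiles = do.call(rbind, qlist))
  row.names(out$summaries) <- row.names(out$quantiles) <- NULL
  if (keep_datasets) out$datasets <- datasets
  out
}

cell_counts_for_predict <- function(model, design, subjects, cells) {
  S <- length(subjects)
  counts <- matrix(0L, S, length(cells))
  if (is.null(design)) {
    for (si in seq_len(S))
      counts[si, ] <- vapply(model$data_cells[[si]],
                             function(dc) length(dc$rt), 0L)
  } else {
    full <- design[design$trial_kind == "full", ]
    if (nrow(full) == 0) stop("design has no full trials", call. = FALSE)
    for (ci in seq_along(cells)) {
      cue <- c(f = "80F", n = "50N", h = "80H")[substr(cells[ci], 1, 1)]
      stim <- c(F = "face", H = "house")[substr(cells[ci], 2, 2)]
      counts[, ci] <- sum(full$cue == cue & full$stimulus == stim)
    }
  }
  counts
}
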