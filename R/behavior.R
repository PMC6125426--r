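#' EWMA fast-guess filter
#'
#' Control-chart removal of fast response-time outliers, applied per
#' subject. Trials are sorted by ascending RT (ties broken by original
#' order) and an exponentially weighted moving average of accuracy is
#' tracked, starting at the chance baseline `p0` (0.5 for a binary task).
#' While responses are fast guesses the chart stays near chance; once
#' responses come under stimulus control it rises above the control limit
#' `p0 + L * sigma_t`, with
#' `sigma_t = sqrt(p0 (1 - p0) * lambda / (2 - lambda) * (1 - (1 -
#' lambda)^(2t)))`. The RT cutoff is placed at the last step where the
#' chart still sits at or below the limit, provided the chart signalled
#' guessing (dipped below the chance baseline) before that point; all
#' trials with RT at or below the cutoff are removed. An accurate dataset
#' whose chart rises from the first trial, or one whose chart never settles
#' above the limit, loses nothing.
#'
#' @param data Behavioral table with columns `subj_idx`, `rt`, `accuracy`
#'   (0/1).
#' @param lambda Smoothing weight in (0, 1].
#' @param L Control-limit width in multiples of the EWMA SD.
#' @param p0 In-control accuracy baseline.
#' @return A list: `data` (filtered table), `cutoffs` (named per-subject RT
#'   cutoffs, 0 when nothing removed), `removed_fraction` (overall),
#'   `removed_per_subject`.
#' @export
ewma_filter <- function(data, lambda = 0.01, L = 1.5, p0 = 0.5) {
  stopifnot(lambda > 0, lambda <= 1, L > 0, p0 > 0, p0 < 1)
  req <- c("subj_idx", "rt", "accuracy")
  if (!all(req %in% names(data)))
    stop("need columns subj_idx, rt, accuracy", call. = FALSE)
  acc <- data$accuracy[!is.na(data$accuracy)]
  if (!all(acc %in% c(0, 1)))
    stop("accuracy must be binary 0/1", call. = FALSE)

  subs <- unique(data$subj_idx)
  cutoffs <- stats::setNames(numeric(length(subs)), as.character(subs))
  keep <- rep(TRUE, nrow(data))
  for (sj in subs) {
    idx <- which(data$subj_idx == sj & !is.na(data$rt))
    if (length(idx) < 20)
      stop(sprintf("subject %s has fewer than 20 trials; EWMA chart unstable",
                   sj), call. = FALSE)
    ord <- idx[order(data$rt[idx])]   # stable: ties keep original order
    a <- data$accuracy[ord]
    n <- length(a)
    w <- numeric(n)
    prev <- p0
    for (t in seq_len(n)) {
      prev <- lambda * a[t] + (1 - lambda) * prev
      w[t] <- prev
    }
    t_seq <- seq_len(n)
    sig <- sqrt(p0 * (1 - p0) * lambda / (2 - lambda) *
                  (1 - (1 - lambda)^(2 * t_seq)))
    below <- which(w <= p0 + L * sig)
    if (length(below) && max(below) < n) {
      pre <- seq_len(max(below))
      # only cut when the chart actually signalled guessing (dipped below
      # the chance baseline) before settling above the control limit; an
      # accurate dataset whose chart rises from the first trial loses
      # nothing
      if (any(w[pre] < p0)) {
        cut <- data$rt[ord[max(below)]]
        cutoffs[as.character(sj)] <- cut
        keep[idx][data$rt[idx] <= cut] <- FALSE
      }
    }
  }
  list(data = data[keep, , drop = FALSE], cutoffs = cutoffs,
       removed_fraction = mean(!keep),
       removed_per_subject = vapply(subs, function(sj)
         mean(!keep[data$subj_idx == sj]), 0))
}

#' Condition summaries of a behavioral dataset
#'
#' Mean accuracy and mean correct-trial RT per cue x stimulus cell, with
#' per-subject cell means and across-subject 95 percent confidence
#' intervals.
#'
#' @param data Behavioral table with columns `subj_idx`, `cue`, `stim`,
#'   `rt`, `accuracy`.
#' @return A list: `cells` (data.frame with cue, stim, n, accuracy, mean CI,
#'   mean_rt_correct and its CI, and a flag for empty RT cells),
#'   `per_subject` (subject x cell means).
#' @export
summarize_conditions <- function(data) {
  req <- c("subj_idx", "cue", "stim", "rt", "accuracy")
  if (!all(req %in% names(data)))
    stop("missing required columns", call. = FALSE)
  per <- aggregate(accuracy ~ subj_idx + cue + stim, data = data, FUN = mean)
  ok <- data$accuracy == 1 & !is.na(data$rt)
  rtper <- aggregate(rt ~ subj_idx + cue + stim, data = data[ok, ],
                     FUN = mean)
  per <- merge(per, rtper, all.x = TRUE)
  ci <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    m <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    m + c(-1, 1) * stats::qt(0.975, length(x) - 1) * se
  }
  cells <- do.call(rbind, lapply(split(per, interaction(per$cue, per$stim,
                                                        drop = TRUE)),
    function(g) {
      acc_ci <- ci(g$accuracy); rt_ci <- ci(g$rt)
      data.frame(cue = g$cue[1], stim = g$stim[1], n_subjects = nrow(g),
                 accuracy = mean(g$accuracy),
                 accuracy_lo = acc_ci[1], accuracy_hi = acc_ci[2],
                 mean_rt_correct = mean(g$rt, na.rm = TRUE),
                 rt_lo = rt_ci[1], rt_hi = rt_ci[2],
                 empty_rt = all(is.na(g$rt)), stringsAsFactors = FALSE)
    }))
  row.names(cells) <- NULL
  ntab <- aggregate(cbind(n = rep(1, nrow(data))) ~ cue + stim, data = data,
                    FUN = sum)
  cells <- merge(cells, ntab, by = c("cue", "stim"))
  if (any(cells$empty_rt))
    warning("some cells have no correct trials; RT summaries are NA there")
  list(cells = cells, per_subject = per)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject factorial ANOVA on a balanced subject x condition
#' table. Effects are tested on orthonormal contrast scores; the
#' Greenhouse-Geisser epsilon for each effect is the standard sample
#' estimator `(tr S)^2 / (q * tr(S^2))` from the covariance matrix S of the
#' contrast scores, and the corrected p-value evaluates F at
#' epsilon-deflated degrees of freedom.
#'
#' @param data Long-format data.frame: one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param factors Character vector of within-subject factor column names
#'   (each with >= 2 levels).
#' @return A data.frame (class `"anova_gg"`) with one row per effect:
#'   F, uncorrected dfs, epsilon, corrected dfs, uncorrected and corrected p.
#' @export
rm_anova_gg <- function(data, dv, subject, factors) {
  if (length(factors) < 1) stop("need at least one factor", call. = FALSE)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop(sprintf("factor '%s' has fewer than 2 levels", f), call. = FALSE)
  }
  data[[subject]] <- factor(data[[subject]])
  levs <- lapply(factors, function(f) levels(data[[f]]))
  names(levs) <- factors
  grid <- expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(factors)), drop = FALSE]
  names(grid) <- factors
  k <- nrow(grid)
  subs <- levels(data[[subject]])
  n <- length(subs)
  # subject x cell matrix, cells in grid order (last factor fastest)
  key_data <- do.call(paste, c(lapply(factors, function(f)
    as.character(data[[f]])), sep = "\r"))
  key_grid <- do.call(paste, c(lapply(factors, function(f)
    as.character(grid[[f]])), sep = "\r"))
  D <- matrix(NA_real_, n, k)
  for (i in seq_along(subs)) {
    di <- data[data[[subject]] == subs[i], ]
    m <- match(key_grid, do.call(paste, c(lapply(factors, function(f)
      as.character(di[[f]])), sep = "\r")))
    if (anyNA(m))
      stop(sprintf("subject %s is missing cells; the design must be complete",
                   subs[i]), call. = FALSE)
    D[i, ] <- di[[dv]][m]
  }

  # orthonormal contrasts per factor; effects are Kronecker products
  contr <- lapply(factors, function(f) {
    C <- stats::contr.helmert(length(levs[[f]]))
    qr.Q(qr(C))
  })
  ones <- lapply(factors, function(f)
    matrix(1 / sqrt(length(levs[[f]])), length(levs[[f]]), 1))
  effects <- unlist(lapply(seq_along(factors), function(ord)
    utils::combn(seq_along(factors), ord, simplify = FALSE)),
    recursive = FALSE)

  rows <- lapply(effects, function(ef) {
    mats <- lapply(seq_along(factors), function(i)
      if (i %in% ef) contr[[i]] else ones[[i]])
    C <- Reduce(kronecker, mats)   # k x q, matches grid order
    T <- D %*% C
    q <- ncol(T)
    tbar <- colMeans(T)
    ss_eff <- n * sum(tbar^2)
    Tc <- sweep(T, 2, tbar)
    ss_err <- sum(Tc^2)
    Fstat <- (ss_eff / q) / (ss_err / (q * (n - 1)))
    Smat <- stats::cov(T)
    eps <- if (q == 1) 1 else sum(diag(Smat))^2 / (q * sum(Smat * Smat))
    eps <- min(max(eps, 1 / q), 1)
    df1 <- q; df2 <- q * (n - 1)
    data.frame(effect = paste(factors[ef], collapse = ":"),
               F = Fstat, df1 = df1, df2 = df2,
               epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
               p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
               p_gg = stats::pf(Fstat, eps * df1, eps * df2,
                                lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("anova_gg", "data.frame")
  out
}

#' Sidak-corrected pairwise comparisons
#'
#' Paired t-tests between condition columns of a subject x condition table,
#' with family-wise Sidak adjustment `p_adj = 1 - (1 - p)^m` over the m
#' comparisons performed.
#'
#' @param cell_table data.frame or matrix, one row per subject, one column
#'   per condition.
#' @param comparisons List of length-2 character (or index) vectors naming
#'   the condition pairs to compare.
#' @return data.frame with t, df, raw and adjusted p per comparison.
#' @export
sidak_pairwise <- function(cell_table, comparisons) {
  m <- length(comparisons)
  if (m == 0) stop("no comparisons requested", call. = FALSE)
  cell_table <- as.data.frame(cell_table)
  rows <- lapply(comparisons, function(cp) {
    x <- cell_table[[cp[[1]]]]; y <- cell_table[[cp[[2]]]]
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(a = as.character(cp[[1]]), b = as.character(cp[[2]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- sidak_adjust(out$p, m)
  out
}

#' @rdname sidak_pairwise
#' @param p Vector of raw p-values.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, 1 - (1 - p)^m)
}
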