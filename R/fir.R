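#' Build a catch-trial FIR design matrix
#'
#' Constructs the finite-impulse-response design for ROI-averaged BOLD time
#' series sampled at `tr` seconds. Each event type contributes one delta
#' regressor per lag, time-locked one TR *before* the event onset (lag 0 is
#' the pre-onset anchor point). Variants:
#' \describe{
#'   \item{separated}{3 cue regressors (cues from catch and full trials
#'     aggregated, locked 1 TR before cue onset) plus 6 stimulus regressors
#'     (cue x stimulus, full trials, locked 1 TR before stimulus onset);
#'     12 lags each - 108 columns.}
#'   \item{combined}{3 catch-trial cue regressors plus 6 full-trial
#'     (cue x stimulus) regressors, all locked 1 TR before cue onset;
#'     14 lags each - 126 columns.}
#'   \item{fast_slow}{like `separated`, but stimulus events are recoded by
#'     the median RT split (see [split_fast_slow()]); events without a speed
#'     code (median ties) are dropped.}
#' }
#'
#' @param events Event table (see [generate_design()]): columns `onset`,
#'   `duration`, `run`, `trial_kind` (`full`/`catch`), `cue`, `stimulus`,
#'   and `speed` for the fast/slow variant. Stimulus onset on full trials is
#'   the cue onset plus the cue duration (3 s by design).
#' @param variant `"separated"`, `"combined"` or `"fast_slow"`.
#' @param lags Number of delta functions per event type (default 12, or 14
#'   for the combined variant).
#' @param tr Repetition time in seconds.
#' @param run_lengths Timepoints per run; defaults to the `run_lengths`
#'   attribute of `events` or, failing that, to covering the last event plus
#'   the FIR window.
#' @param cue_duration Cue-phase duration in seconds (stimulus onset
#'   offset), default 3.
#' @return An object of class `"fir_design"`: the 0/1 matrix `X`
#'   (timepoints x regressors), `labels` (event type and lag per column),
#'   the run index per row, and the settings used.
#' @export
build_fir_design <- function(events, variant = c("separated", "combined",
                                                 "fast_slow"),
                             lags = NULL, tr = 1.5, run_lengths = NULL,
                             cue_duration = 3) {
  variant <- match.arg(variant)
  if (is.null(lags)) lags <- if (variant == "combined") 14L else 12L
  req <- c("onset", "duration", "run", "trial_kind", "cue", "stimulus")
  if (!all(req %in% names(events)))
    stop("event table lacks required columns", call. = FALSE)
  cue_code <- cue_short[as.character(events$cue)]
  if (any(is.na(cue_code))) stop("unknown cue codes", call. = FALSE)

  # enumerate (event type, onset, run)
  evs <- switch(variant,
    separated = , fast_slow = {
      cue_ev <- data.frame(type = paste0("cue_", cue_code),
                           onset = events$onset, run = events$run)
      full <- events$trial_kind == "full"
      st <- events[full, , drop = FALSE]
      stim_code <- stim_short[as.character(st$stimulus)]
      type <- paste0("stim_", cue_code[full], stim_code, recycle0 = TRUE)
      if (variant == "fast_slow") {
        if (!"speed" %in% names(st))
          stop("fast_slow variant requires a 'speed' column ",
               "(see split_fast_slow)", call. = FALSE)
        keep <- !is.na(st$speed)
        st <- st[keep, , drop = FALSE]
        type <- paste0("stim_", stim_code[keep], "_", st$speed,
                       recycle0 = TRUE)
      }
      rbind(cue_ev,
            data.frame(type = type, onset = st$onset + cue_duration,
                       run = st$run))
    },
    combined = {
      catch <- events$trial_kind == "catch"
      rbind(
        data.frame(type = paste0("catchcue_", cue_code[catch],
                                 recycle0 = TRUE),
                   onset = events$onset[catch], run = events$run[catch]),
        data.frame(type = paste0("full_", cue_code[!catch],
                                 stim_short[as.character(
                                   events$stimulus[!catch])],
                                 recycle0 = TRUE),
                   onset = events$onset[!catch], run = events$run[!catch]))
    })

  runs <- sort(unique(events$run))
  if (is.null(run_lengths)) run_lengths <- attr(events, "run_lengths")
  if (is.null(run_lengths)) {
    run_lengths <- vapply(runs, function(r) {
      e <- events[events$run == r, ]
      ceiling((max(e$onset + e$duration) + lags * tr) / tr)
    }, 0)
  }
  if (length(run_lengths) != length(runs))
    stop("run_lengths must have one entry per run", call. = FALSE)
  row_offset <- c(0, cumsum(run_lengths))[seq_along(runs)]
  names(row_offset) <- as.character(runs)
  n_rows <- sum(run_lengths)

  types <- sort(unique(evs$type))
  labels <- data.frame(event_type = rep(types, each = lags),
                       lag = rep(seq_len(lags) - 1L, length(types)),
                       stringsAsFactors = FALSE)
  X <- matrix(0, n_rows, nrow(labels))
  colnames(X) <- paste0(labels$event_type, ".lag", labels$lag)

  run_of_row <- rep(runs, run_lengths)
  for (i in seq_len(nrow(evs))) {
    r <- as.character(evs$run[i])
    tp <- round(evs$onset[i] / tr) + 1L  # 1-based timepoint of onset
    anchor <- tp - 1L                    # locked 1 TR before onset
    if (anchor < 1L)
      stop("event too close to run start for the pre-onset lock",
           call. = FALSE)
    if (anchor + lags - 1L > run_lengths[match(evs$run[i], runs)])
      stop("event extends past the run end", call. = FALSE)
    col0 <- (match(evs$type[i], types) - 1L) * lags
    rows <- row_offset[r] + anchor + seq_len(lags) - 1L
    if (any(X[cbind(rows[1], col0 + 1L)] == 1))
      stop("overlapping duplicate events of type ", evs$type[i],
           call. = FALSE)
    X[cbind(rows, col0 + seq_len(lags))] <- 1
  }
  structure(list(X = X, labels = labels, tr = tr, lags = lags,
                 variant = variant, run = run_of_row,
                 run_lengths = stats::setNames(run_lengths,
                                               as.character(runs))),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("FIR design (%s): %d timepoints x %d columns (%d event types x %d lags), TR = %gs\n",
              x$variant, nrow(x$X), ncol(x$X),
              length(unique(x$labels$event_type)), x$lags, x$tr))
  invisible(x)
}

#' Fit an FIR GLM to ROI time series
#'
#' Ordinary least squares estimation of the per-lag responses. Each run's
#' series is converted to percent signal change about its run mean
#' (`100 * (y - mean) / mean`) and run-specific intercepts are added, so
#' coefficients are in percent-signal-change units; set `psc = FALSE` to fit
#' the raw series (exact coefficient recovery on series constructed as
#' `design x coefficients`). Per-lag standard errors come from the residual
#' variance.
#'
#' @param series Numeric vector (single run) or list of per-run vectors,
#'   concatenating to the design's rows.
#' @param design An [build_fir_design()] object.
#' @param psc Convert to percent signal change per run (default TRUE).
#' @return An object of class `"fir_fit"`: `timecourses` (data.frame:
#'   condition, lag, estimate, se), `peaks` (per condition, see
#'   [extract_peak()]), `sigma2`, `df_residual`.
#' @export
fit_fir_glm <- function(series, design, psc = TRUE) {
  stopifnot(inherits(design, "fir_design"))
  if (!is.list(series)) series <- list(series)
  y <- unlist(series, use.names = FALSE)
  if (length(y) != nrow(design$X))
    stop("series length does not match design rows", call. = FALSE)
  if (psc) {
    y <- unlist(lapply(series, function(r) 100 * (r - mean(r)) / mean(r)),
                use.names = FALSE)
  }
  runs <- unique(design$run)
  Xint <- sapply(runs, function(r) as.numeric(design$run == r))
  colnames(Xint) <- paste0("baseline_run", runs)
  X <- cbind(design$X, Xint)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(X, y)
  df_res <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df_res
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))[seq_len(ncol(design$X))]
  est <- fit$coefficients[seq_len(ncol(design$X))]
  tc <- data.frame(condition = design$labels$event_type,
                   lag = design$labels$lag,
                   estimate = unname(est), se = unname(se),
                   stringsAsFactors = FALSE)
  peaks <- do.call(rbind, lapply(split(tc, tc$condition), function(g) {
    g <- g[order(g$lag), ]
    pk <- extract_peak(g$estimate)
    data.frame(condition = g$condition[1], peak = pk$magnitude,
               peak_lag = pk$lag, stringsAsFactors = FALSE)
  }))
  row.names(peaks) <- NULL
  structure(list(timecourses = tc, peaks = peaks, sigma2 = sigma2,
                 df_residual = df_res, tr = design$tr, lags = design$lags),
            class = "fir_fit")
}

#' @export
print.fir_fit <- function(x, ...) {
  cat(sprintf("FIR fit: %d conditions x %d lags (TR = %gs)\n",
              nrow(x$peaks), x$lags, x$tr))
  print(x$peaks)
  invisible(x)
}

#' Peak magnitude of an estimated timecourse
#'
#' Maximum of the estimated response over post-onset lags. Lag 0 is the
#' pre-onset anchor point and is excluded from the search; ties return the
#' earliest maximal lag.
#'
#' @param tc Numeric vector of per-lag estimates (lag 0 first).
#' @return A list with `magnitude` and `lag` (0-based).
#' @examples
#' extract_peak(c(0, 0.1, 0.5, 0.3))
#' @export
extract_peak <- function(tc) {
  if (!length(tc)) stop("empty timecourse", call. = FALSE)
  if (length(tc) == 1) return(list(magnitude = tc[1], lag = 0L))
  post <- tc[-1]
  i <- which.max(post)
  list(magnitude = unname(post[i]), lag = as.integer(i))
}

#' Cue/stimulus regressor separability report
#'
#' Quantifies how well a design can distinguish cue-evoked from
#' stimulus-evoked activity: for every cue-regressor/stimulus-regressor
#' column pair, the absolute correlation, summarized by its maximum, plus a
#' variance-inflation summary over all task columns. When a second design on
#' the same timebase is supplied (e.g. the same schedule without catch
#' trials or jitter), a comparison is returned.
#'
#' @param design An [build_fir_design()] object.
#' @param reference Optional second design to compare against.
#' @return A list with `max_cue_stim_cor`, `vif` (per column; `Inf` when the
#'   design is singular), `singular` flag; and when `reference` is given,
#'   `reference` (its own report) and `lower_than_reference`.
#' @export
regressor_separability <- function(design, reference = NULL) {
  rep1 <- separability_one(design)
  if (is.null(reference)) return(rep1)
  if (nrow(reference$X) != nrow(design$X))
    stop("designs have mismatched row counts", call. = FALSE)
  rep2 <- separability_one(reference)
  c(rep1, list(reference = rep2,
               lower_than_reference =
                 rep1$max_cue_stim_cor < rep2$max_cue_stim_cor))
}

separability_one <- function(design) {
  stopifnot(inherits(design, "fir_design"))
  lab <- design$labels$event_type
  is_cue <- grepl("^(cue|catchcue)_", lab)
  is_stim <- grepl("^(stim|full)_", lab)
  X <- design$X
  keep <- apply(X, 2, stats::sd) > 0
  Xk <- X[, keep, drop = FALSE]
  cue_k <- is_cue[keep]; stim_k <- is_stim[keep]
  C <- suppressWarnings(stats::cor(Xk))
  max_cor <- if (any(cue_k) && any(stim_k))
    max(abs(C[cue_k, stim_k, drop = FALSE]), na.rm = TRUE) else NA_real_
  R <- C
  vif <- rep(NA_real_, ncol(X)); names(vif) <- colnames(X)
  singular <- FALSE
  ev_min <- tryCatch(min(eigen(R, symmetric = TRUE,
                               only.values = TRUE)$values),
                     error = function(e) 0)
  if (ev_min < 1e-10) {
    singular <- TRUE
    vif[keep] <- Inf
  } else {
    vif[keep] <- diag(solve(R))
  }
  list(max_cue_stim_cor = max_cor, vif = vif, singular = singular,
       n_constant_columns = sum(!keep))
}

#' Median RT split of stimulus events
#'
#' Recodes full-trial stimulus events as Fast or Slow by the per-subject
#' median of correct-trial RTs: Fast means faster than the median, Slow
#' slower; trials exactly at the median are dropped (speed `NA`). Catch
#' trials and error/no-response trials get speed `NA`.
#'
#' @param events Event table with columns `trial_kind`, `rt`, `accuracy`,
#'   and optionally `subj_idx` (one subject assumed if absent).
#' @return The event table with a `speed` column (`"fast"`, `"slow"`, `NA`).
#' @examples
#' ev <- data.frame(trial_kind = "full", rt = c(1, 2, 3, 4), accuracy = 1,
#'                  onset = 1:4, duration = 9, run = 1,
#'                  cue = "50N", stimulus = "face")
#' split_fast_slow(ev)$speed
#' @export
split_fast_slow <- function(events) {
  if (!all(c("trial_kind", "rt", "accuracy") %in% names(events)))
    stop("need columns trial_kind, rt, accuracy", call. = FALSE)
  sub <- if ("subj_idx" %in% names(events)) events$subj_idx else
    rep(1L, nrow(events))
  events$speed <- NA_character_
  for (sj in unique(sub)) {
    i <- which(sub == sj & events$trial_kind == "full" &
                 !is.na(events$rt) & events$accuracy %in% 1)
    if (length(i) < 4)
      stop(sprintf("subject %s has fewer than 4 usable trials", sj),
           call. = FALSE)
    med <- stats::median(events$rt[i])
    events$speed[i[events$rt[i] < med]] <- "fast"
    events$speed[i[events$rt[i] > med]] <- "slow"
  }
  events
}

#' Grow ROIs around peaks of a statistical map
#'
#' Smooths a 3-D Z map with a Gaussian kernel (`fwhm_mm`), finds strict
#' 26-neighbour local maxima above `z_thresh` (labelled `face`) and minima
#' below `-z_thresh` (labelled `house`), enforces a minimum peak separation
#' of `radius_mm`, grows a sphere of `radius_mm` around each peak, and drops
#' member voxels that do not exceed the threshold (with matching sign) in
#' the *original* unsmoothed map.
#'
#' @param stat_map 3-D numeric array of Z values.
#' @param voxel_size_mm Voxel edge length in mm (isotropic).
#' @param fwhm_mm Smoothing kernel FWHM in mm (0 = no smoothing).
#' @param z_thresh Two-sided Z threshold (default 1.96).
#' @param radius_mm Sphere radius in mm (default 8).
#' @return A list of ROI masks, each a list with `voxels` (n x 3 index
#'   matrix), `peak` (index triplet), `peak_z` (smoothed value) and `label`;
#'   empty list when nothing is suprathreshold.
#' @export
localize_rois <- function(stat_map, voxel_size_mm = 2, fwhm_mm = 4,
                          z_thresh = 1.96, radius_mm = 8) {
  stopifnot(length(dim(stat_map)) == 3, all(is.finite(stat_map)),
            fwhm_mm >= 0)
  sm <- if (fwhm_mm > 0)
    gauss_smooth3d(stat_map, fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm)
  else stat_map
  dims <- dim(sm)

  peaks <- local_extrema3d(sm, z_thresh)
  if (nrow(peaks) == 0) return(list())
  # minimum separation: greedy by |Z| descending
  peaks <- peaks[order(-abs(peaks$z)), , drop = FALSE]
  kept <- peaks[0, ]
  for (i in seq_len(nrow(peaks))) {
    if (nrow(kept) == 0) { kept <- peaks[i, , drop = FALSE]; next }
    d <- sqrt((kept$x - peaks$x[i])^2 + (kept$y - peaks$y[i])^2 +
                (kept$z_ix - peaks$z_ix[i])^2) * voxel_size_mm
    if (all(d >= radius_mm)) kept <- rbind(kept, peaks[i, ])
  }

  r_vox <- radius_mm / voxel_size_mm
  off <- as.matrix(expand.grid(x = -floor(r_vox):floor(r_vox),
                               y = -floor(r_vox):floor(r_vox),
                               z = -floor(r_vox):floor(r_vox)))
  off <- off[sqrt(rowSums(off^2)) <= r_vox, , drop = FALSE]

  rois <- list()
  for (i in seq_len(nrow(kept))) {
    ctr <- c(kept$x[i], kept$y[i], kept$z_ix[i])
    vox <- sweep(off, 2, ctr, `+`)
    inb <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
      vox[, 2] >= 1 & vox[, 2] <= dims[2] &
      vox[, 3] >= 1 & vox[, 3] <= dims[3]
    vox <- vox[inb, , drop = FALSE]
    vals <- stat_map[vox]
    sel <- if (kept$z[i] > 0) vals > z_thresh else vals < -z_thresh
    vox <- vox[sel, , drop = FALSE]
    if (nrow(vox) == 0) next
    rois[[length(rois) + 1]] <- list(
      voxels = unname(vox), peak = unname(ctr), peak_z = kept$z[i],
      label = if (kept$z[i] > 0) "face" else "house")
  }
  rois
}

gauss_smooth3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  smooth_along <- function(a, dim_i) {
    d <- dim(a)
    perm <- switch(dim_i, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = dim(ap)[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      shift <- j - r - 1L
      src <- seq_len(n) + shift
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    ap2 <- array(out, dim(ap))
    aperm(ap2, order(perm))
  }
  a <- arr
  for (i in 1:3) a <- smooth_along(a, i)
  a
}

local_extrema3d <- function(a, thresh) {
  d <- dim(a)
  res <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
    v <- a[x, y, z]
    if (abs(v) <= thresh) next
    nv <- a[cbind(x + nb[, 1], y + nb[, 2], z + nb[, 3])]
    if (v > 0 && all(v > nv))
      res[[length(res) + 1]] <- data.frame(x = x, y = y, z_ix = z, z = v)
    else if (v < 0 && all(v < nv))
      res[[length(res) + 1]] <- data.frame(x = x, y = y, z_ix = z, z = v)
  }
  if (!length(res)) return(data.frame(x = integer(), y = integer(),
                                      z_ix = integer(), z = numeric()))
  do.call(rbind, res)
}

#' Prediction/surprise decomposition of event-related peaks
#'
#' Least-squares decomposition of the six condition peaks (3 cues x 2
#' stimuli) into a baseline, a prediction component that scales with the
#' cued probability of the region's preferred category on all trials, and a
#' surprise component equal to `1 - P(presented stimulus | cue)` on
#' preferred-stimulus trials and 0 otherwise. The surprise:prediction weight
#' ratio summarizes the relative contribution of the two unit types.
#'
#' @param peaks Named numeric of length 6 with names `fF, nF, hF, fH, nH,
#'   hH` (cue letter then stimulus letter), or a data.frame with columns
#'   `cue` (f/n/h), `stim` (F/H) and `peak`.
#' @param prob_face Cued probability of a face per cue,
#'   default `c(f = 0.8, n = 0.5, h = 0.2)`.
#' @param preferred The region's preferred category, `"face"` or `"house"`.
#' @return An object of class `"pc_fit"`: `baseline`, `weight_prediction`,
#'   `weight_surprise`, `ratio` (surprise/prediction; `NA` when the
#'   prediction weight is 0), `rss`, `fitted`.
#' @export
fit_pc_decomposition <- function(peaks,
                                 prob_face = c(f = 0.8, n = 0.5, h = 0.2),
                                 preferred = c("face", "house")) {
  preferred <- match.arg(preferred)
  cells <- c("fF", "nF", "hF", "fH", "nH", "hH")
  if (is.data.frame(peaks)) {
    nm <- paste0(peaks$cue, peaks$stim)
    y <- stats::setNames(peaks$peak, nm)[cells]
  } else y <- peaks[cells]
  if (anyNA(y)) stop("need peaks for all six cue x stimulus cells",
                     call. = FALSE)
  if (length(unique(prob_face)) == 1)
    stop("identical cue probabilities: decomposition unidentifiable",
         call. = FALSE)
  cue <- substr(cells, 1, 1); stim <- substr(cells, 2, 2)
  p_pref <- if (preferred == "face") prob_face[cue] else 1 - prob_face[cue]
  p_presented <- ifelse(stim == "F", prob_face[cue], 1 - prob_face[cue])
  pref_stim <- if (preferred == "face") "F" else "H"
  surprise <- ifelse(stim == pref_stim, 1 - p_presented, 0)
  X <- cbind(baseline = 1, prediction = unname(p_pref),
             surprise = unname(surprise))
  fit <- lm.fit(X, unname(y))
  b <- fit$coefficients
  structure(list(baseline = unname(b["baseline"]),
                 weight_prediction = unname(b["prediction"]),
                 weight_surprise = unname(b["surprise"]),
                 ratio = if (abs(b["prediction"]) < 1e-12) NA_real_ else
                   unname(b["surprise"] / b["prediction"]),
                 rss = sum(fit$residuals^2),
                 fitted = stats::setNames(as.numeric(X %*% b), cells)),
            class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf(
    "Prediction/surprise decomposition: baseline %.3f, w_P %.3f, w_S %.3f (ratio %.2f, rss %.2g)\n",
    x$baseline, x$weight_prediction, x$weight_surprise, x$ratio, x$rss))
  invisible(x)
}
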