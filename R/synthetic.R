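#' Experimental design configuration
#'
#' The probabilistic face/house task layout: 600 trials split across five
#' runs of 120; 200 trials per cue type (80F, 50N, 80H) of which 40 are
#' cue-only catch trials; on 80% cues the 160 full trials split 128 valid /
#' 32 invalid, and the neutral cue splits 80 face / 80 house. The cue phase
#' lasts 3 s, the task phase 6 s (so full trials last 9 s, catch trials
#' 3 s), and inter-trial rest periods are exponentially distributed multiples
#' of the TR (1.5 s) between 0 and 15 s with mean 1.92 s.
#'
#' @param n_runs,trials_per_run,trials_per_cue,catch_per_cue Design counts.
#' @param valid_trials,invalid_trials Full-trial validity split per 80% cue.
#' @param neutral_face,neutral_house Full-trial split for the neutral cue.
#' @param cue_duration,task_duration,tr Durations in seconds.
#' @param jitter_max,jitter_mean Rest-period range and target mean (s).
#' @param lead_in Rest before the first trial of a run (s).
#' @param tail Rest appended after the last trial (s), covering the FIR
#'   window.
#' @return A validated list of class `"design_config"`.
#' @export
design_config <- function(n_runs = 5, trials_per_run = 120,
                          trials_per_cue = 200, catch_per_cue = 40,
                          valid_trials = 128, invalid_trials = 32,
                          neutral_face = 80, neutral_house = 80,
                          cue_duration = 3, task_duration = 6, tr = 1.5,
                          jitter_max = 15, jitter_mean = 1.92,
                          lead_in = 3, tail = 21) {
  cfg <- list(n_runs = n_runs, trials_per_run = trials_per_run,
              trials_per_cue = trials_per_cue, catch_per_cue = catch_per_cue,
              valid_trials = valid_trials, invalid_trials = invalid_trials,
              neutral_face = neutral_face, neutral_house = neutral_house,
              cue_duration = cue_duration, task_duration = task_duration,
              tr = tr, jitter_max = jitter_max, jitter_mean = jitter_mean,
              lead_in = lead_in, tail = tail)
  n_full <- trials_per_cue - catch_per_cue
  if (3 * trials_per_cue != n_runs * trials_per_run)
    stop("cue trial counts do not match run structure", call. = FALSE)
  if (valid_trials + invalid_trials != n_full)
    stop("validity split does not sum to the full-trial count", call. = FALSE)
  if (neutral_face + neutral_house != n_full)
    stop("neutral split does not sum to the full-trial count", call. = FALSE)
  if (any(c(cue_duration, task_duration, jitter_max, lead_in) %% tr != 0))
    stop("durations must be multiples of the TR", call. = FALSE)
  class(cfg) <- "design_config"
  cfg
}

# geometric success parameter for TR-multiple jitter, calibrated so the
# truncated-geometric mean equals the target mean
jitter_q <- function(cfg) {
  kmax <- cfg$jitter_max / cfg$tr
  target <- cfg$jitter_mean / cfg$tr
  f <- function(q) {
    k <- 0:kmax
    w <- q^k
    sum(k * w) / sum(w) - target
  }
  stats::uniroot(f, c(1e-6, 1 - 1e-6))$root
}

sample_jitter <- function(n, cfg) {
  if (cfg$jitter_max == 0 || cfg$jitter_mean == 0) return(numeric(n))
  q <- jitter_q(cfg)
  k <- 0:(cfg$jitter_max / cfg$tr)
  w <- q^k
  cfg$tr * sample(k, n, replace = TRUE, prob = w / sum(w))
}

#' Generate the event table of one subject's session
#'
#' Produces trial-level timing with the exact printed counts of
#' [design_config()]: per-cue catch and full-trial numbers, validity splits,
#' a seeded random trial order within runs, and truncated-geometric rest
#' periods at TR multiples. Stimulus onset on full trials is fixed at the
#' end of the 3-s cue phase (un-jittered); catch trials end after the cue.
#'
#' @param config A [design_config()].
#' @param seed Integer seed (reproducible tables).
#' @return A data.frame of class `"event_table"`: `onset`, `duration`,
#'   `run`, `trial`, `trial_kind` (`full`/`catch`), `cue`
#'   (`80F`/`50N`/`80H`), `stimulus` (`face`/`house`/`none`), `iti`; with a
#'   `run_lengths` attribute (timepoints per run) and the config attached.
#' @export
generate_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  set.seed(as.integer(seed))
  mk <- function(cue, kind, stim, n)
    if (n > 0) data.frame(cue = cue, trial_kind = kind, stimulus = stim,
                          n = seq_len(n))[, 1:3] else NULL
  trials <- rbind(
    mk("80F", "catch", "none", config$catch_per_cue),
    mk("80F", "full", "face", config$valid_trials),
    mk("80F", "full", "house", config$invalid_trials),
    mk("50N", "catch", "none", config$catch_per_cue),
    mk("50N", "full", "face", config$neutral_face),
    mk("50N", "full", "house", config$neutral_house),
    mk("80H", "catch", "none", config$catch_per_cue),
    mk("80H", "full", "house", config$valid_trials),
    mk("80H", "full", "face", config$invalid_trials))
  n <- nrow(trials)
  trials <- trials[sample.int(n), ]
  trials$run <- rep(seq_len(config$n_runs), each = config$trials_per_run)
  trials$trial <- unlist(lapply(seq_len(config$n_runs),
                                function(r) seq_len(config$trials_per_run)))
  trials$duration <- ifelse(trials$trial_kind == "catch",
                            config$cue_duration,
                            config$cue_duration + config$task_duration)
  trials$iti <- sample_jitter(n, config)

  onset <- numeric(n)
  run_lengths <- integer(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    i <- which(trials$run == r)
    t0 <- config$lead_in
    for (j in i) {
      onset[j] <- t0
      t0 <- t0 + trials$duration[j] + trials$iti[j]
    }
    run_lengths[r] <- as.integer((t0 + config$tail) / config$tr)
  }
  trials$onset <- onset
  out <- trials[, c("onset", "duration", "run", "trial", "trial_kind",
                    "cue", "stimulus", "iti")]
  row.names(out) <- NULL
  attr(out, "run_lengths") <- run_lengths
  attr(out, "config") <- config
  class(out) <- c("event_table", "data.frame")
  out
}

#' Generative group ground truth for the cue-bias models
#'
#' Draws per-subject parameter sets around configurable group means, with
#' the multi-stage (MSM) condition structure: starting points vary by cue
#' and drift rates by cue and stimulus. The default effects follow the
#' qualitative pattern the models are meant to detect: all starting points
#' above the midpoint with `z_h < z_n < z_f` (neutral anchored at 0.66),
#' face drifts essentially unmodulated by the cue, and the house drift
#' attenuated after face cues; house drifts are stronger in magnitude than
#' face drifts.
#'
#' @param n_subjects Number of subjects (default 19).
#' @param group_means Named list of group means: `a`, `tr`, `z` (named
#'   f/n/h), `v` (named fF, nF, hF, fH, nH, hH).
#' @param group_sds Between-subject SDs for a, tr, z, v.
#' @param sv,sz,st Group-level inter-trial variability.
#' @param seed Integer seed.
#' @return An object of class `"ground_truth"`: per-subject parameter lists
#'   plus the generating group values.
#' @export
default_ground_truth <- function(n_subjects = 19,
                                 group_means = list(
                                   a = 1.6, tr = 0.6,
                                   z = c(f = 0.72, n = 0.66, h = 0.58),
                                   v = c(fF = 1.0, nF = 1.0, hF = 0.9,
                                         fH = -0.85, nH = -1.2, hH = -1.25)),
                                 group_sds = list(a = 0.15, tr = 0.08,
                                                  z = 0.04, v = 0.15),
                                 sv = 0.4, sz = 0.06, st = 0.15,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lo | x >= hi))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  subjects <- lapply(seq_len(n_subjects), function(s) {
    z <- vapply(group_means$z, function(m)
      rtnorm(1, m, group_sds$z, sz / 2 + 0.01, 1 - sz / 2 - 0.01), 0)
    v <- vapply(group_means$v, function(m)
      stats::rnorm(1, m, group_sds$v), 0)
    list(a = rtnorm(1, group_means$a, group_sds$a, 0.2, Inf),
         tr = rtnorm(1, group_means$tr, group_sds$tr, st / 2 + 0.01, Inf),
         z = z, v = v)
  })
  structure(list(subjects = subjects, group_means = group_means,
                 group_sds = group_sds, sv = sv, sz = sz, st = st,
                 n_subjects = n_subjects),
            class = "ground_truth")
}

#' Simulate behavioral data for a design
#'
#' Forward-simulates choices and response times for every full trial of the
#' design, per subject, using that subject's condition parameters from the
#' ground truth and the diffusion simulator ([simulate_ddm()]). Catch trials
#' produce no behavior. Trials exceeding the 6-s response window are marked
#' `no_response` (rt and accuracy `NA`).
#'
#' @param design An [generate_design()] event table (shared across
#'   subjects), or a list of per-subject tables.
#' @param truth A [default_ground_truth()] object.
#' @param seed Integer seed.
#' @param dt Simulator step (s).
#' @param deadline Response window (s).
#' @return Behavioral data.frame: `subj_idx`, `cue`, `stim`, `response`,
#'   `rt`, `accuracy`, `run`, `trial`.
#' @export
simulate_behavior <- function(design, truth, seed = 1L, dt = 1e-4,
                              deadline = 6) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(as.integer(seed))
  designs <- if (is.data.frame(design))
    rep(list(design), truth$n_subjects) else design
  if (length(designs) != truth$n_subjects)
    stop("need one design (or one per subject)", call. = FALSE)
  seeds <- sample.int(.Machine$integer.max - 1L, truth$n_subjects * 6)
  cue_l <- c(`80F` = "f", `50N` = "n", `80H` = "h")
  stim_l <- c(face = "F", house = "H")
  out <- vector("list", truth$n_subjects)
  k <- 0L
  for (s in seq_len(truth$n_subjects)) {
    d <- designs[[s]]
    full <- d[d$trial_kind == "full", ]
    pars <- truth$subjects[[s]]
    full$response <- NA_character_
    full$rt <- NA_real_
    for (cue in names(cue_l)) for (stim in names(stim_l)) {
      k <- k + 1L
      i <- which(full$cue == cue & full$stimulus == stim)
      if (!length(i)) next
      p <- ddm_params(a = pars$a,
                      z = pars$z[[cue_l[[cue]]]],
                      v = pars$v[[paste0(cue_l[[cue]], stim_l[[stim]])]],
                      tr = pars$tr, sv = truth$sv, sz = truth$sz,
                      st = truth$st)
      sim <- simulate_ddm(p, length(i), deadline = deadline,
                          seed = seeds[k], dt = dt)
      full$response[i] <- ifelse(sim$choice == "upper", "face",
                                 ifelse(sim$choice == "lower", "house",
                                        "no_response"))
      full$rt[i] <- sim$rt
    }
    out[[s]] <- data.frame(subj_idx = s, cue = full$cue, stim = full$stimulus,
                           response = full$response, rt = full$rt,
                           accuracy = ifelse(full$response == "no_response",
                                             NA_integer_,
                                             as.integer(full$response ==
                                                          full$stimulus)),
                           run = full$run, trial = full$trial,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Canonical double-gamma HRF
#'
#' @param t Time in seconds (vector).
#' @param a1,b1,a2,b2,c Shape/rate parameters of the positive lobe and the
#'   undershoot and the undershoot weight.
#' @return HRF values normalized to unit peak.
#' @export
hrf_double_gamma <- function(t, a1 = 6, b1 = 1, a2 = 16, b2 = 1, c = 1 / 6) {
  h <- function(x) stats::dgamma(x, shape = a1, rate = b1) -
    c * stats::dgamma(x, shape = a2, rate = b2)
  peak <- max(h(seq(0, 30, by = 0.01)))
  ifelse(t < 0, 0, h(t) / peak)
}

#' BOLD generator configuration
#'
#' @param amplitudes Named percent-signal-change amplitudes for the nine
#'   event types of the separated-events model (`cue_f`, `cue_n`, `cue_h`,
#'   `stim_fF`, `stim_nF`, `stim_hF`, `stim_fH`, `stim_nH`, `stim_hH`).
#'   The defaults describe a face-preferring region: cue responses scale
#'   with the cued face probability (prediction weight 0.25 above a 0.10
#'   baseline) and face-stimulus responses scale with surprise,
#'   `1 - P(face | cue)`, with weight 0.5 above a 0.15 baseline - a 2:1
#'   surprise-to-prediction ratio. House-stimulus responses mirror the
#'   surprise pattern.
#' @param noise_sd White-noise SD (percent signal units).
#' @param ar AR(1) coefficient of the noise, in (-1, 1).
#' @param drift Peak-to-peak linear drift per run (percent signal units).
#' @param baseline Raw-signal baseline level.
#' @param tr Repetition time (s).
#' @param hrf List of [hrf_double_gamma()] parameters.
#' @return A list of class `"bold_config"`.
#' @export
bold_config <- function(amplitudes = c(cue_f = 0.3, cue_n = 0.225,
                                       cue_h = 0.15, stim_fF = 0.25,
                                       stim_nF = 0.40, stim_hF = 0.55,
                                       stim_fH = 0.55, stim_nH = 0.40,
                                       stim_hH = 0.25),
                        noise_sd = 0.25, ar = 0.3, drift = 0.2,
                        baseline = 100, tr = 1.5,
                        hrf = list(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                   c = 1 / 6)) {
  stopifnot(all(is.finite(amplitudes)), abs(ar) < 1, noise_sd >= 0)
  structure(list(amplitudes = amplitudes, noise_sd = noise_sd, ar = ar,
                 drift = drift, baseline = baseline, tr = tr, hrf = hrf),
            class = "bold_config")
}

#' Synthesize ROI-averaged BOLD time series for a design
#'
#' Builds the noise-free percent-signal response as a sum of
#' amplitude-scaled HRFs at every cue onset (cue events, all trials) and
#' stimulus onset (full trials), samples it at the TR, adds AR(1) noise and
#' a linear drift, and embeds it around the raw baseline level. The
#' generating amplitudes are returned for recovery tests.
#'
#' @param design An [generate_design()] event table.
#' @param config A [bold_config()].
#' @param seed Integer seed.
#' @param cue_duration Stimulus-onset offset (s), matching the design.
#' @return A list: `series` (per-run raw signal), `pct` (per-run noise-free
#'   percent signal), `truth` (amplitudes), `run_lengths`.
#' @export
synthesize_bold <- function(design, config = bold_config(), seed = 1L,
                            cue_duration = 3) {
  set.seed(as.integer(seed))
  amp <- config$amplitudes
  need <- c("cue_f", "cue_n", "cue_h", paste0("stim_", rep(c("f", "n", "h"),
                                                           2),
                                              rep(c("F", "H"), each = 3)))
  if (!all(need %in% names(amp)))
    stop("amplitudes must name all nine event types", call. = FALSE)
  run_lengths <- attr(design, "run_lengths")
  if (is.null(run_lengths))
    stop("design lacks a run_lengths attribute", call. = FALSE)
  tr <- config$tr
  runs <- sort(unique(design$run))
  hrf_par <- config$hrf

  series <- pct <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    d <- design[design$run == runs[ri], ]
    nt <- run_lengths[ri]
    tgrid <- (seq_len(nt) - 1) * tr
    last_end <- max(d$onset + d$duration)
    if (max(tgrid) < last_end + 9)
      stop("run too short for the last event plus the HRF tail",
           call. = FALSE)
    sig <- numeric(nt)
    addev <- function(onset, a) {
      h <- do.call(hrf_double_gamma, c(list(t = tgrid - onset), hrf_par))
      sig <<- sig + a * h
    }
    for (i in seq_len(nrow(d))) {
      cue <- cue_short[[as.character(d$cue[i])]]
      addev(d$onset[i], amp[[paste0("cue_", cue)]])
      if (d$trial_kind[i] == "full") {
        stim <- stim_short[[as.character(d$stimulus[i])]]
        addev(d$onset[i] + cue_duration, amp[[paste0("stim_", cue, stim)]])
      }
    }
    noise <- numeric(nt)
    if (config$noise_sd > 0) {
      e <- stats::rnorm(nt, 0, config$noise_sd * sqrt(1 - config$ar^2))
      noise[1] <- stats::rnorm(1, 0, config$noise_sd)
      for (t in 2:nt) noise[t] <- config$ar * noise[t - 1] + e[t]
    }
    dr <- config$drift * (seq_len(nt) - (nt + 1) / 2) / nt
    pct[[ri]] <- sig
    series[[ri]] <- config$baseline * (1 + (sig + noise + dr) / 100)
  }
  list(series = series, pct = pct, truth = amp, run_lengths = run_lengths)
}

#' Noise-degraded stimulus movie
#'
#' Generates the 6-s dynamic stimulus: a procedurally drawn face-like or
#' house-like source pattern (512 x 512 grayscale) standardized to zero mean
#' and unit variance, combined per frame with an independent standard
#' Gaussian noise field as `sqrt(1 - w) * Z + sqrt(w) * noise`, so the noise
#' carries fraction `w` of the pixel variance (the operationalization of
#' "67% noise"), then affinely rescaled to [0, 1] with constants shared by
#' all frames (the per-frame SNR is constant; only the spatial noise pattern
#' changes).
#'
#' @param type `"face"` or `"house"` (procedural source pattern).
#' @param noise_w Noise variance share in [0, 1], default 0.67.
#' @param n_frames Number of frames (default 90; 15 frames/s x 6 s).
#' @param size Frame edge length in pixels (default 512).
#' @param seed Integer seed.
#' @return A `size x size x n_frames` array in [0, 1] with attributes
#'   `source` (the standardized source image) and `noise_w`.
#' @export
generate_stimulus_movie <- function(type = c("face", "house"),
                                    noise_w = 0.67, n_frames = 90,
                                    size = 512, seed = 1L) {
  type <- match.arg(type)
  if (noise_w < 0 || noise_w > 1)
    stop("noise_w must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  src <- procedural_image(type, size)
  z <- (src - mean(src)) / stats::sd(src)
  stack <- array(sqrt(noise_w) * stats::rnorm(size * size * n_frames),
                 dim = c(size, size, n_frames))
  stack <- stack + as.vector(sqrt(1 - noise_w) * z)
  lo <- min(stack); hi <- max(stack)
  stack <- (stack - lo) / (hi - lo)
  attr(stack, "source") <- z
  attr(stack, "noise_w") <- noise_w
  stack
}

# crude grayscale patterns standing in for licensed photographs; the
# category is a label, not a perceptual claim
procedural_image <- function(type, size) {
  x <- matrix(rep(seq(-1, 1, length.out = size), size), size)
  y <- t(x)
  if (type == "face") {
    img <- exp(-((x / 0.62)^2 + (y / 0.8)^2)^2)           # head
    img <- img - 0.5 * exp(-(((x - 0.25) / 0.1)^2 + ((y + 0.2) / 0.07)^2)) -
      0.5 * exp(-(((x + 0.25) / 0.1)^2 + ((y + 0.2) / 0.07)^2))  # eyes
    img <- img - 0.4 * exp(-((x / 0.22)^2 + ((y - 0.45) / 0.05)^2)) # mouth
    img <- img + 0.25 * exp(-((x / 0.05)^2 + ((y - 0.05) / 0.2)^2)) # nose
  } else {
    img <- as.numeric(abs(x) < 0.6 & y > -0.15 & y < 0.75)        # facade
    img <- img + 0.8 * as.numeric(y <= -0.15 & y > -0.6 - 0.75 * -abs(x) &
                                    abs(x) < 0.75 & y > -0.6 + 0.75 * abs(x) - 0.45)
    img <- img - 0.6 * as.numeric(abs(x - 0.25) < 0.12 & y > 0.3 & y < 0.75) # door
    img <- img - 0.5 * as.numeric(abs(x + 0.3) < 0.1 & abs(y - 0.05) < 0.1)  # window
  }
  img
}

#' Synthetic 3-D statistical map
#'
#' Sum of Gaussian bumps plus white noise on a voxel grid; the generating
#' bump table is attached for localization tests.
#'
#' @param bumps List of bumps, each `list(center = c(x, y, z) in mm,
#'   peak_z = height, width_mm = Gaussian SD)`.
#' @param dim Grid size in voxels (length 3).
#' @param voxel_size_mm Voxel edge (mm).
#' @param noise_sd White-noise SD (Z units).
#' @param seed Integer seed.
#' @param min_separation_mm Warn when bump centers are closer than this.
#' @return 3-D array with attribute `bumps`.
#' @export
generate_stat_map <- function(bumps, dim = c(40, 40, 30), voxel_size_mm = 2,
                              noise_sd = 0, seed = 1L,
                              min_separation_mm = 16) {
  set.seed(as.integer(seed))
  if (length(bumps) >= 2) {
    ctrs <- do.call(rbind, lapply(bumps, `[[`, "center"))
    dmat <- as.matrix(stats::dist(ctrs))
    if (any(dmat[upper.tri(dmat)] < min_separation_mm))
      warning("bump centers closer than the minimum separation")
  }
  co <- lapply(dim, function(d) (seq_len(d) - 1) * voxel_size_mm)
  arr <- array(0, dim)
  for (b in bumps) {
    if (any(b$center < 0) || any(b$center > (dim - 1) * voxel_size_mm))
      stop("bump center outside the grid", call. = FALSE)
    dx2 <- outer(co[[1]], co[[2]], function(a, bb)
      (a - b$center[1])^2 + (bb - b$center[2])^2)
    for (k in seq_len(dim[3])) {
      arr[, , k] <- arr[, , k] + b$peak_z *
        exp(-(dx2 + (co[[3]][k] - b$center[3])^2) / (2 * b$width_mm^2))
    }
  }
  if (noise_sd > 0) arr <- arr + array(stats::rnorm(prod(dim), 0, noise_sd),
                                       dim)
  attr(arr, "bumps") <- bumps
  arr
}
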