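#' Cue-bias model specification
#'
#' Declares which drift-diffusion parameters vary with the probabilistic cue:
#' the prior-bias model (`"PBM"`) lets the starting point vary by cue
#' (`z_f`, `z_n`, `z_h`) with stimulus-specific drifts shared across cues
#' (`v_F`, `v_H`); the dynamic-bias model (`"DBM"`) lets the drift rate vary
#' by cue and stimulus (`v_fF` ... `v_hH`) with a single starting point `z`;
#' the multi-stage model (`"MSM"`) frees both sets. Boundary separation `a`
#' and non-decision time `tr` are estimated per subject in every variant;
#' inter-trial variability parameters (`sv`, `sz`, `st`) are group-level
#' only. PBM and DBM are restrictions of the MSM.
#'
#' @param name One of `"PBM"`, `"DBM"`, `"MSM"`.
#' @return An object of class `"hddm_spec"`.
#' @examples
#' model_spec("PBM")
#' @export
model_spec <- function(name = c("MSM", "PBM", "DBM")) {
  name <- match.arg(name)
  cues <- c("f", "n", "h")
  stims <- c("F", "H")
  z_types <- if (name == "DBM") "z" else paste0("z_", cues)
  v_types <- if (name == "PBM") paste0("v_", stims) else
    paste0("v_", rep(cues, each = 2), rep(stims, 3))
  subject_types <- c("a", "tr", z_types, v_types)

  cells <- paste0(rep(cues, 2), rep(stims, each = 3)) # fF nF hF fH nH hH
  cell_map <- lapply(cells, function(cl) {
    cue <- substr(cl, 1, 1); stim <- substr(cl, 2, 2)
    c(z = if (name == "DBM") "z" else paste0("z_", cue),
      v = if (name == "PBM") paste0("v_", stim) else paste0("v_", cue, stim))
  })
  names(cell_map) <- cells

  # cells whose likelihood depends on each subject-level parameter
  affected <- lapply(subject_types, function(p) {
    if (p %in% c("a", "tr")) return(cells)
    hit <- vapply(cell_map, function(m) p %in% m, logical(1))
    cells[hit]
  })
  names(affected) <- subject_types

  structure(list(name = name, subject_types = subject_types,
                 cells = cells, cell_map = cell_map, affected = affected),
            class = "hddm_spec")
}

#' @export
print.hddm_spec <- function(x, ...) {
  cat("Cue-bias DDM specification:", x$name, "\n")
  cat("  subject-level parameters:", paste(x$subject_types, collapse = ", "),
      "\n  group-level variability: sv, sz, st\n")
  invisible(x)
}

# prior class of a subject-level parameter type
type_class <- function(p) {
  if (p == "a") "a" else if (p == "tr") "tr"
  else if (startsWith(p, "z")) "z" else "v"
}

#' Default prior specification
#'
#' Weakly informative priors for the hierarchical cue-bias models, in the
#' style of common hierarchical DDM toolboxes. Group means: boundary
#' `a ~ Normal(1.5, 1)` truncated to (0, Inf); starting points
#' `~ Normal(0.5, 0.25)` truncated to (0.05, 0.95); drifts `~ Normal(0, 2)`;
#' non-decision time `~ Normal(0.3, 0.2)` truncated to (0, 1). Group SDs are
#' Half-Normal(0.5). Inter-trial variability (group level only):
#' `sv ~ Half-Normal(1)`, `sz ~ Uniform(0, 0.4)`, `st ~ Uniform(0, 0.3)`.
#' Subject-level parameters are Normal around the group mean, truncated to
#' the parameter's domain.
#'
#' @return A nested list, serializable to YAML/JSON.
#' @export
default_priors <- function() {
  list(
    group_mean = list(
      a  = list(mean = 1.5, sd = 1,    lower = 0,    upper = Inf),
      z  = list(mean = 0.5, sd = 0.25, lower = 0.05, upper = 0.95),
      v  = list(mean = 0,   sd = 2,    lower = -Inf, upper = Inf),
      tr = list(mean = 0.3, sd = 0.2,  lower = 0,    upper = 1)),
    group_sd = list(scale = 0.5),
    sv = list(scale = 1),
    sz = list(upper = 0.4),
    st = list(upper = 0.3),
    subject_domain = list(
      a = c(0.01, Inf), z = c(0.02, 0.98), v = c(-Inf, Inf), tr = c(0, Inf))
  )
}

log_dtnorm <- function(x, mean, sd, lower, upper) {
  if (x <= lower || x >= upper) return(-Inf)
  stats::dnorm(x, mean, sd, log = TRUE) -
    log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd))
}

# vectorized over x (the sampler's inner loops)
log_dtnorm_sum <- function(x, mean, sd, lower, upper) {
  if (any(x <= lower | x >= upper)) return(-Inf)
  sum(stats::dnorm(x, mean, sd, log = TRUE)) -
    length(x) * log(stats::pnorm(upper, mean, sd) -
                      stats::pnorm(lower, mean, sd))
}

log_dhalfnorm <- function(x, scale) {
  if (x <= 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

log_dunif0 <- function(x, upper) {
  if (x < 0 || x > upper) return(-Inf)
  -log(upper)
}

# ---- behavioral table normalization ------------------------------------

cue_short <- c("80F" = "f", "50N" = "n", "80H" = "h",
               "f" = "f", "n" = "n", "h" = "h")
stim_short <- c(face = "F", house = "H", F = "F", H = "H")

normalize_behavior <- function(data) {
  req <- c("subj_idx", "cue", "stim", "response", "rt")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("behavioral table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- data[!is.na(data$rt) & !(data$response %in% c("none", "no_response")), ]
  cue <- cue_short[as.character(data$cue)]
  stim <- stim_short[as.character(data$stim)]
  if (any(is.na(cue))) stop("unknown cue codes", call. = FALSE)
  if (any(is.na(stim))) stop("unknown stimulus codes", call. = FALSE)
  data.frame(subj = data$subj_idx, cue = unname(cue), stim = unname(stim),
             upper = response_to_upper(as.character(data$response)),
             rt = as.numeric(data$rt), stringsAsFactors = FALSE)
}

#' Build a hierarchical cue-bias model
#'
#' Assembles the data structures and the log-posterior of a hierarchical
#' drift-diffusion model in which cues may bias the starting point, the
#' drift rate, or both. The face response maps to the upper boundary. The
#' returned object carries per-subject, per-condition-cell trial slices, a
#' cell log-likelihood evaluator and a full log-posterior callable over the
#' complete parameter set (group hyperparameters plus subject-level
#' parameters).
#'
#' @param data Behavioral table with columns `subj_idx`, `cue` (80F/50N/80H),
#'   `stim` (face/house), `response` (face/house), `rt` (s). Extra columns
#'   are ignored; no-response rows are dropped.
#' @param spec A [model_spec()] or a model name (`"PBM"`, `"DBM"`, `"MSM"`).
#' @param priors A prior specification, see [default_priors()].
#' @param err Series truncation error of the likelihood.
#' @param penalty Log-density penalty for zero-density trials.
#' @return An object of class `"hddm_model"`.
#' @export
build_model <- function(data, spec = "MSM", priors = default_priors(),
                        err = 1e-7, penalty = -1e6) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "hddm_spec"))
  beh <- normalize_behavior(data)
  subjects <- sort(unique(beh$subj))
  S <- length(subjects)
  cells <- spec$cells

  data_cells <- lapply(subjects, function(sj) {
    d <- beh[beh$subj == sj, ]
    cl <- lapply(cells, function(c6) {
      i <- d$cue == substr(c6, 1, 1) & d$stim == substr(c6, 2, 2)
      if (!any(i))
        stop(sprintf("subject %s has no trials in cell %s", sj, c6),
             call. = FALSE)
      list(rt = d$rt[i], up = as.integer(d$upper[i]))
    })
    names(cl) <- cells
    cl
  })
  names(data_cells) <- as.character(subjects)

  types <- spec$subject_types
  group_names <- c(paste0("mu_", types), paste0("sigma_", types),
                   "sv", "sz", "st")
  subj_names <- as.vector(outer(types, subjects,
                                function(p, s) paste0(p, "[", s, "]")))

  checksum <- list(n = nrow(beh), sum_rt = round(sum(beh$rt), 6),
                   sum_up = sum(beh$upper), subjects = S)

  loglik_cell <- function(s, cell, subjrow, varpars) {
    m <- spec$cell_map[[cell]]
    dc <- data_cells[[s]][[cell]]
    ddm_loglik_cpp(dc$rt, dc$up,
                   subjrow[["a"]], subjrow[[m[["z"]]]], subjrow[[m[["v"]]]],
                   subjrow[["tr"]], varpars[["sv"]], varpars[["sz"]],
                   varpars[["st"]], err, penalty)
  }

  log_prior <- function(group, subj) {
    lp <- 0
    for (p in types) {
      cls <- type_class(p)
      pm <- priors$group_mean[[cls]]
      lp <- lp + log_dtnorm(group[[paste0("mu_", p)]], pm$mean, pm$sd,
                            pm$lower, pm$upper)
      lp <- lp + log_dhalfnorm(group[[paste0("sigma_", p)]],
                               priors$group_sd$scale)
      if (!is.finite(lp)) return(-Inf)
      dom <- priors$subject_domain[[cls]]
      for (s in seq_len(nrow(subj)))
        lp <- lp + log_dtnorm(subj[s, p], group[[paste0("mu_", p)]],
                              group[[paste0("sigma_", p)]], dom[1], dom[2])
      if (!is.finite(lp)) return(-Inf)
    }
    lp <- lp + log_dhalfnorm(group[["sv"]], priors$sv$scale) +
      log_dunif0(group[["sz"]], priors$sz$upper) +
      log_dunif0(group[["st"]], priors$st$upper)
    lp
  }

  log_likelihood <- function(subj, varpars) {
    ll <- 0
    for (s in seq_len(S)) {
      row <- subj[s, ]
      for (cell in cells)
        ll <- ll + loglik_cell(s, cell, row, varpars)
    }
    ll
  }

  log_posterior <- function(group, subj) {
    lp <- log_prior(group, subj)
    if (!is.finite(lp)) return(-Inf)
    lp + log_likelihood(subj, c(sv = group[["sv"]], sz = group[["sz"]],
                                st = group[["st"]]))
  }

  structure(list(spec = spec, priors = priors, subjects = subjects,
                 n_subjects = S, data_cells = data_cells,
                 n_trials = nrow(beh), checksum = checksum,
                 group_names = group_names, subj_names = subj_names,
                 err = err, penalty = penalty,
                 loglik_cell = loglik_cell, log_prior = log_prior,
                 log_likelihood = log_likelihood,
                 log_posterior = log_posterior),
            class = "hddm_model")
}

#' @export
print.hddm_model <- function(x, ...) {
  cat(sprintf("Hierarchical %s model: %d subjects, %d trials, %d parameters\n",
              x$spec$name, x$n_subjects, x$n_trials,
              length(x$group_names) + length(x$subj_names)))
  invisible(x)
}
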