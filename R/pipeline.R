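PIPELINE_STAGES <- c("design", "behavior", "filter", "fit", "compare",
                     "ppc", "bold", "fir", "report")

# per-stage substream of the global seed, so stages can be re-run
# independently yet reproducibly
stage_seed <- function(seed, stage) {
  i <- match(stage, PIPELINE_STAGES)
  as.integer((as.numeric(seed) + 10007 * i) %% (2^31 - 1))
}

#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end synthetic run: the design, the
#' generative ground truth, the fast-guess filter, the model list and
#' sampler settings, posterior predictive and FIR settings, and stage
#' toggles. The default sampler settings are sized for a quick desk-scale
#' run; raise `draws`/`burnin`/`chains` for production fits.
#'
#' @param seed Global seed, expanded into per-stage substreams.
#' @param n_subjects Simulated subjects.
#' @param design A [design_config()].
#' @param ewma EWMA filter settings (lambda, L, p0).
#' @param models Model variants to fit.
#' @param sampler Sampler settings (chains, draws, burnin).
#' @param ppc Posterior predictive settings (n_datasets, dt).
#' @param bold A [bold_config()] (or plain list of its fields).
#' @param stages Named logical stage toggles.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_subjects = 4L,
                       design = design_config(),
                       ewma = list(lambda = 0.01, L = 1.5, p0 = 0.5),
                       models = c("PBM", "DBM", "MSM"),
                       sampler = list(chains = 2L, draws = 300L,
                                      burnin = 200L),
                       ppc = list(n_datasets = 20L, dt = 1e-3),
                       bold = bold_config(),
                       stages = list(design = TRUE, behavior = TRUE,
                                     filter = TRUE, fit = TRUE,
                                     compare = TRUE, ppc = TRUE, bold = TRUE,
                                     fir = TRUE, report = TRUE)) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              design = design, ewma = ewma,
              models = as.character(models), sampler = sampler, ppc = ppc,
              bold = bold, stages = stages)
  class(cfg) <- "run_config"
  cfg
}

#' Save or load a run configuration (YAML)
#'
#' `load_run_config(save_run_config(cfg, path))` reproduces `cfg` exactly;
#' both sides canonicalize through [run_config()].
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return The path (save) or the configuration (load).
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$design <- unclass(out$design)
  out$bold <- lapply(unclass(out$bold), function(f)
    if (is.numeric(f) && !is.null(names(f))) as.list(f) else f)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bold <- raw$bold
  for (f in c("amplitudes", "hrf"))
    if (!is.null(bold[[f]])) bold[[f]] <- unlist(bold[[f]])
  run_config(seed = raw$seed, n_subjects = raw$n_subjects,
             design = do.call(design_config, raw$design),
             ewma = raw$ewma, models = raw$models,
             sampler = raw$sampler, ppc = raw$ppc,
             bold = do.call(bold_config,
                            c(list(amplitudes = bold$amplitudes),
                              bold[setdiff(names(bold),
                                           c("amplitudes", "hrf"))],
                              list(hrf = as.list(bold$hrf)))),
             stages = raw$stages)
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in dependency order: design generation,
#' behavior simulation, EWMA filtering, hierarchical model fitting, DIC
#' comparison, posterior predictive checks, BOLD synthesis and FIR
#' estimation, and report generation. Artifacts are written under
#' `out_dir`; the returned manifest records per-stage status, outputs and
#' seeds. A disabled prerequisite causes downstream stages to be skipped
#' with a reason rather than failing.
#'
#' @param config A [run_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return The run manifest (list), also written to `manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cueddm",
                   version = as.character(utils::packageVersion("cueddm")),
                   seed = config$seed, out_dir = out_dir,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  state <- new.env(parent = emptyenv())
  done <- character()

  add_stage <- function(name, status, outputs = character(),
                        reason = NULL, extra = NULL) {
    st <- list(name = name, status = status,
               seed = stage_seed(config$seed, name),
               outputs = as.list(outputs))
    if (!is.null(reason)) st$reason <- reason
    if (!is.null(extra)) st <- c(st, extra)
    manifest$stages[[name]] <<- st
    if (identical(status, "completed")) done <<- c(done, name)
  }

  run_stage <- function(name, deps, fun) {
    if (!isTRUE(config$stages[[name]])) {
      add_stage(name, "skipped", reason = "disabled in config")
      return(invisible())
    }
    missing_dep <- setdiff(deps, done)
    if (length(missing_dep)) {
      add_stage(name, "skipped",
                reason = paste("requires stage(s):",
                               paste(missing_dep, collapse = ", ")))
      return(invisible())
    }
    res <- tryCatch(fun(stage_seed(config$seed, name)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      add_stage(name, "failed", reason = conditionMessage(res))
    } else {
      add_stage(name, "completed", outputs = res$outputs,
                extra = res$extra)
    }
  }

  run_stage("design", character(), function(seed) {
    state$design <- generate_design(config$design, seed = seed)
    f <- file.path(out_dir, "design.tsv")
    write_events_tsv(state$design, f)
    list(outputs = f)
  })

  run_stage("behavior", "design", function(seed) {
    state$truth <- default_ground_truth(config$n_subjects, seed = seed)
    state$behavior <- simulate_behavior(state$design, state$truth,
                                        seed = seed, dt = 1e-3)
    f <- file.path(out_dir, "behavior.tsv")
    write_behavior_tsv(state$behavior, f)
    list(outputs = f)
  })

  run_stage("filter", "behavior", function(seed) {
    ok <- state$behavior[state$behavior$response != "no_response", ]
    fl <- ewma_filter(ok, lambda = config$ewma$lambda, L = config$ewma$L,
                      p0 = config$ewma$p0)
    state$filtered <- fl$data
    f1 <- file.path(out_dir, "behavior_filtered.tsv")
    f2 <- file.path(out_dir, "filter_log.json")
    write_behavior_tsv(fl$data, f1)
    jsonlite::write_json(list(cutoffs = as.list(fl$cutoffs),
                              removed_fraction = fl$removed_fraction),
                         f2, auto_unbox = TRUE, digits = NA)
    list(outputs = c(f1, f2),
         extra = list(removed_fraction = fl$removed_fraction))
  })

  run_stage("fit", "filter", function(seed) {
    fits <- list()
    outs <- character()
    for (m in config$models) {
      fit <- fit_hddm(state$filtered, model = m,
                      chains = config$sampler$chains,
                      draws = config$sampler$draws,
                      burnin = config$sampler$burnin,
                      seed = stage_seed(seed, "fit"))
      fits[[m]] <- fit
      f <- file.path(out_dir, paste0("fit_", m, ".json"))
      write_fit_result_json(fit$dic, f)
      fd <- file.path(out_dir, paste0("draws_", m, ".tsv"))
      utils::write.table(as_draws_df(fit), fd, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, f, fd)
    }
    state$fits <- fits
    list(outputs = outs)
  })

  run_stage("compare", "fit", function(seed) {
    cmp <- compare_models(lapply(state$fits, `[[`, "dic"))
    state$comparison <- cmp
    f <- file.path(out_dir, "dic_table.tsv")
    utils::write.table(cmp$ranking, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(outputs = f, extra = list(winner = cmp$winner))
  })

  run_stage("ppc", "fit", function(seed) {
    best <- if (!is.null(state$comparison)) state$comparison$winner else
      config$models[length(config$models)]
    pp <- posterior_predict(state$fits[[best]],
                            n_datasets = config$ppc$n_datasets,
                            seed = seed, dt = config$ppc$dt)
    f1 <- file.path(out_dir, "ppc_summaries.tsv")
    f2 <- file.path(out_dir, "ppc_quantiles.tsv")
    utils::write.table(pp$summaries, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pp$quantiles, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(outputs = c(f1, f2), extra = list(model = best))
  })

  run_stage("bold", "design", function(seed) {
    state$bold <- synthesize_bold(state$design, config$bold, seed = seed)
    f <- file.path(out_dir, "bold_roi.tsv")
    utils::write.table(
      data.frame(run = rep(seq_along(state$bold$series),
                           vapply(state$bold$series, length, 0L)),
                 signal = unlist(state$bold$series)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(outputs = f)
  })

  run_stage("fir", "bold", function(seed) {
    des <- build_fir_design(state$design, "separated")
    fit <- fit_fir_glm(state$bold$series, des)
    state$fir <- fit
    f1 <- file.path(out_dir, "fir_timecourses.tsv")
    f2 <- file.path(out_dir, "fir_peaks.tsv")
    utils::write.table(fit$timecourses, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(fit$peaks, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(outputs = c(f1, f2))
  })

  run_stage("report", character(), function(seed) {
    f <- file.path(out_dir, "report.md")
    render_report(manifest, f)
    list(outputs = f)
  })

  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest$path <- f
  invisible(manifest)
}

#' Render a run report from a manifest
#'
#' Assembles a markdown summary (stage status, DIC comparison, behavioral
#' condition summary, FIR peak table) purely from the artifacts the
#' manifest lists; nothing is recomputed.
#'
#' @param manifest A [run_pipeline()] manifest, or the path of a
#'   `manifest.json`.
#' @param path Output file (default `report.md` next to the manifest).
#' @return The report path.
#' @export
make_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    mdir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
    manifest$out_dir <- mdir
  }
  if (is.null(path)) path <- file.path(manifest$out_dir, "report.md")
  render_report(manifest, path)
  path
}

render_report <- function(manifest, path) {
  lines <- c(sprintf("# Synthetic cue-bias run (seed %s)", manifest$seed), "",
             "## Stages", "")
  for (st in manifest$stages) {
    if (identical(st$name, "report")) next  # the report does not list itself
    l <- sprintf("- %s: %s", st$name, st$status)
    if (!is.null(st$reason)) l <- paste0(l, " (", st$reason, ")")
    lines <- c(lines, l)
  }
  grab <- function(stage, pattern) {
    st <- manifest$stages[[stage]]
    if (is.null(st) || !identical(st$status, "completed")) return(NULL)
    hits <- grep(pattern, unlist(st$outputs), value = TRUE)
    if (!length(hits)) return(NULL)
    hits[1]
  }
  tsv_block <- function(file, title) {
    if (is.null(file) || !file.exists(file)) return(NULL)
    tab <- utils::read.table(file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    c("", paste("##", title), "", "```",
      utils::capture.output(print(utils::head(tab, 20))), "```")
  }
  lines <- c(lines,
             tsv_block(grab("compare", "dic_table"), "Model comparison (DIC)"),
             tsv_block(grab("ppc", "ppc_summaries"),
                       "Posterior predictive condition summaries"),
             tsv_block(grab("fir", "fir_peaks"), "FIR peak magnitudes"))
  writeLines(lines, path)
  invisible(path)
}
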