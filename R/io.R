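#' Read and write behavioral and event tables
#'
#' Behavioral tables use the columnar layout common to hierarchical DDM
#' tooling (`subj_idx`, `cue`, `stim`, `response`, `rt`, `accuracy`, ...);
#' event tables use a BIDS-events-like TSV with `onset` and `duration`
#' first. Both are plain tab-separated text.
#'
#' @param x Table to write.
#' @param path File path.
#' @param run_lengths Optional per-run timepoint counts to re-attach when
#'   reading an event table.
#' @return The file path (writers) or a data.frame (readers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_behavior_tsv <- function(x, path) {
  req <- c("subj_idx", "cue", "stim", "response", "rt", "accuracy")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_behavior_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @export
write_events_tsv <- function(x, path) {
  stopifnot(all(c("onset", "duration") %in% names(x)))
  first <- c("onset", "duration")
  x <- x[, c(first, setdiff(names(x), first))]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_events_tsv <- function(path, run_lengths = NULL) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(run_lengths)) attr(ev, "run_lengths") <- run_lengths
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Posterior draws as a long table
#'
#' @param samples An `"hddm_samples"` or `"hddm"` object.
#' @return data.frame with columns `parameter`, `chain`, `draw`, `value`.
#' @export
as_draws_df <- function(samples) {
  if (inherits(samples, "hddm")) samples <- samples$samples
  stopifnot(inherits(samples, "hddm_samples"))
  do.call(rbind, lapply(seq_along(samples$chains), function(ch) {
    m <- samples$chains[[ch]]
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
}

#' Serialize a DIC fit result to JSON
#'
#' @param x A [fit_result()].
#' @param path File path.
#' @export
write_fit_result_json <- function(x, path) {
  stopifnot(inherits(x, "fit_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
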