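# Case inclusion filtering for cohort assembly.

#' Apply case-inclusion criteria to a cohort
#'
#' Retains the samples that pass every enabled criterion: subtype specified,
#' primary tumor (recurrent/secondary excluded), complete expression data for
#' the selected target genes, no treatment prior to resection, and — in
#' three-class mode — exclusion of neural-labelled cases (the neural subtype
#' reflects normal-tissue content rather than a tumor class).
#'
#' @param x Wide expression tibble (or genes x samples matrix); may contain
#'   `NA` cells, which the completeness criterion acts on.
#' @param meta Metadata tibble with columns `sample`, `subtype`,
#'   `sample_type`, `prior_treatment` (see [read_sample_metadata()]). Every
#'   matrix sample must have a record.
#' @param targets Genes whose completeness is required; default all genes in
#'   `x`.
#' @param require_subtype,primary_only,require_complete,untreated_only,exclude_neural
#'   Logical switches for the individual criteria (all `TRUE` by default).
#' @return The filtered expression tibble, with a per-sample report attached
#'   as attribute `case_report` (retrieve with [case_report()]): columns
#'   `sample`, `retained`, `reason` (`NA` for retained samples; otherwise the
#'   first failed criterion).
#' @export
filter_cases <- function(x, meta, targets = NULL,
                         require_subtype = TRUE, primary_only = TRUE,
                         require_complete = TRUE, untreated_only = TRUE,
                         exclude_neural = TRUE) {
  m <- expr_mat(x)
  samples <- colnames(m)
  if (!all(c("sample", "subtype", "sample_type", "prior_treatment") %in% names(meta))) {
    abort("metadata must have columns sample, subtype, sample_type, prior_treatment")
  }
  missing <- setdiff(samples, meta$sample)
  if (length(missing)) {
    abort(paste0("samples without metadata: ", paste(missing, collapse = ", ")))
  }
  meta <- meta[match(samples, meta$sample), ]
  targets <- targets %||% rownames(m)
  absent <- setdiff(targets, rownames(m))
  if (length(absent)) {
    abort(paste0("target genes absent from matrix: ", paste(absent, collapse = ", ")))
  }

  reason <- rep(NA_character_, length(samples))
  flag <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  if (require_subtype) {
    reason <- flag(is.na(meta$subtype) | meta$subtype == "unknown", "subtype unspecified")
  }
  if (exclude_neural) {
    reason <- flag(meta$subtype == "Neural", "neural subtype")
  }
  if (primary_only) {
    reason <- flag(meta$sample_type != "primary", "not a primary tumor")
  }
  if (untreated_only) {
    reason <- flag(isTRUE_vec(meta$prior_treatment), "treated prior to resection")
  }
  if (require_complete) {
    incomplete <- colSums(is.na(m[targets, , drop = FALSE])) > 0
    reason <- flag(incomplete, "incomplete target data")
  }
  reason <- unname(reason)
  retained <- is.na(reason)
  report <- tibble::tibble(sample = samples, retained = retained, reason = reason)
  out <- expr_tbl(m[, retained, drop = FALSE])
  attr(out, "case_report") <- report
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Retrieve the per-sample retention report of [filter_cases()]
#' @param x The filtered expression tibble returned by [filter_cases()].
#' @return Tibble with columns `sample`, `retained`, `reason`.
#' @export
case_report <- function(x) {
  rep <- attr(x, "case_report")
  if (is.null(rep)) abort("no case report attached; was this produced by filter_cases()?")
  rep
}
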