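# qPCR CT table ingestion: replicate aggregation and QC flagging.

validate_ct_values <- function(ct) {
  bad <- which(!is.finite(ct) | ct <= 0 | ct > 45)
  if (length(bad)) {
    abort(paste0("CT values outside (0, 45]: ", length(bad),
                 " offending measurement(s), first = ", ct[bad[1]]))
  }
  invisible(TRUE)
}

#' Aggregate replicate CT measurements
#'
#' Collapses a long-format CT table (one row per replicate measurement) to one
#' CT per gene x sample, flagging gene/sample pairs whose replicate standard
#' deviation exceeds `max_replicate_sd`. Flagged values are kept, never
#' dropped: high replicate scatter is a QC signal for the bench, not an
#' exclusion rule.
#'
#' @param ct Long tibble with columns `sample`, `gene`, `ct` (and optionally
#'   `replicate`).
#' @param ref_genes Reference (endogenous control) genes that must be present
#'   for every sample; default ACTB, GAPDH, YWHAZ.
#' @param replicate_policy `"mean"` (default) or `"median"` aggregation across
#'   replicates.
#' @param max_replicate_sd Replicate standard-deviation threshold, in PCR
#'   cycles, above which a gene/sample pair is QC-flagged (default 0.5).
#' @return A `ct_tbl`: tibble with columns `sample`, `gene`, `ct`,
#'   `n_replicates`, `replicate_sd`, `qc_flag`, carrying the reference gene
#'   list as attribute `ref_genes`. Use [ct_qc()] for the flagged subset.
#' @export
aggregate_ct <- function(ct, ref_genes = REF_GENES,
                         replicate_policy = c("mean", "median"),
                         max_replicate_sd = 0.5) {
  replicate_policy <- match.arg(replicate_policy)
  if (!all(c("sample", "gene", "ct") %in% names(ct))) {
    abort("CT table must have columns `sample`, `gene`, `ct`")
  }
  validate_ct_values(ct$ct)
  agg_fun <- if (replicate_policy == "mean") mean else stats::median
  out <- ct |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      replicate_sd = if (dplyr::n() > 1) sd(.data$ct) else 0,
      ct = agg_fun(.data$ct),
      .groups = "drop"
    ) |>
    dplyr::mutate(qc_flag = .data$replicate_sd > max_replicate_sd) |>
    dplyr::select("sample", "gene", "ct", "n_replicates", "replicate_sd", "qc_flag")
  missing_ref <- out |>
    dplyr::distinct(.data$sample) |>
    tidyr::crossing(gene = ref_genes) |>
    dplyr::anti_join(out, by = c("sample", "gene"))
  if (nrow(missing_ref)) {
    abort(paste0("reference gene(s) missing: ",
                 paste(paste0(missing_ref$gene, " for ", missing_ref$sample),
                       collapse = "; ")))
  }
  structure(out, ref_genes = ref_genes, replicate_policy = replicate_policy,
            max_replicate_sd = max_replicate_sd,
            class = c("ct_tbl", class(out)))
}

#' Read a qPCR CT table from delimited text
#'
#' Accepts long format (columns `sample`, `gene`, `replicate`, `ct`) or wide
#' format (a `gene` column plus one numeric column per sample; one row per
#' replicate measurement, repeated gene rows = replicates). Replicates are
#' aggregated per `replicate_policy` and QC-flagged via [aggregate_ct()].
#'
#' @inheritParams aggregate_ct
#' @param path Path to the CT file (TSV; comma auto-detected).
#' @return A `ct_tbl` tibble; see [aggregate_ct()].
#' @export
read_ct_table <- function(path, ref_genes = REF_GENES,
                          replicate_policy = c("mean", "median"),
                          max_replicate_sd = 0.5) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  if (all(c("sample", "gene", "ct") %in% names(raw))) {
    long <- raw
  } else if ("gene" %in% names(raw)) {
    long <- tidyr::pivot_longer(raw, -"gene", names_to = "sample",
                                values_to = "ct")
  } else {
    abort("CT file must be long format (sample, gene, ct) or wide with a `gene` column")
  }
  long$ct <- as.numeric(long$ct)
  aggregate_ct(long, ref_genes = ref_genes, replicate_policy = replicate_policy,
               max_replicate_sd = max_replicate_sd)
}

#' QC report of replicate scatter
#'
#' @param ct A `ct_tbl` from [read_ct_table()] or [aggregate_ct()].
#' @return The gene/sample rows whose replicate standard deviation exceeded
#'   the QC threshold.
#' @export
ct_qc <- function(ct) {
  if (!inherits(ct, "ct_tbl")) abort("`ct` must be a ct_tbl")
  dplyr::filter(tibble::as_tibble(ct), .data$qc_flag)
}
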