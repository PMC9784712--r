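# Normalisation chain: delta-CT against the geometric mean of reference genes,
# per-gene cohort centering, per-gene standard score.

#' Convert aggregated CT values to log2 expression
#'
#' For each sample the reference level is the geometric mean of the reference
#' genes' CT values; each target gene's delta-CT is its CT minus that
#' reference. The returned value is `-delta-CT`, i.e. the log2 of the
#' `2^-delta-CT` relative fold change, so direction matches log-space array
#' data: higher value = more transcript, and one extra PCR cycle lowers the
#' value by exactly 1.
#'
#' @param ct A `ct_tbl` from [read_ct_table()]/[aggregate_ct()], or a long
#'   tibble with columns `sample`, `gene`, `ct` (reference genes then taken
#'   from `ref_genes`).
#' @param ref_genes Reference genes; defaults to the `ct_tbl`'s own attribute,
#'   else ACTB/GAPDH/YWHAZ.
#' @return Wide expression tibble of target genes (reference genes are
#'   consumed by the normalisation and not returned).
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample = "S1", gene = c("EGFR", "ACTB", "GAPDH", "YWHAZ"),
#'   ct = c(25, 20, 20, 20))
#' ct_to_log_expression(aggregate_ct(ct))  # delta-CT 5 -> log2 expression -5
ct_to_log_expression <- function(ct, ref_genes = NULL) {
  ref_genes <- ref_genes %||% attr(ct, "ref_genes") %||% REF_GENES
  if (!all(c("sample", "gene", "ct") %in% names(ct))) {
    abort("CT input must have columns `sample`, `gene`, `ct`")
  }
  validate_ct_values(ct$ct)
  refs <- ct |>
    dplyr::filter(.data$gene %in% ref_genes) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_ref = dplyr::n_distinct(.data$gene),
                     ref_ct = exp(mean(log(.data$ct))), .groups = "drop")
  all_samples <- unique(ct$sample)
  missing <- setdiff(all_samples, refs$sample[refs$n_ref == length(ref_genes)])
  if (length(missing)) {
    abort(paste0("reference genes incomplete for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  targets <- ct |>
    dplyr::filter(!.data$gene %in% ref_genes) |>
    dplyr::left_join(refs, by = "sample") |>
    dplyr::mutate(log2_expr = -(.data$ct - .data$ref_ct)) |>
    dplyr::select("sample", "gene", "log2_expr")
  wide <- tidyr::pivot_wider(targets, names_from = "sample",
                             values_from = "log2_expr")
  expr_tbl(expr_mat(wide))
}

#' Center each gene on its cohort mean
#'
#' Subtracts the per-gene cohort mean (x - x-bar), the normalisation applied
#' to a new cohort before classification. Idempotent.
#'
#' @param x Wide expression tibble (or genes x samples matrix), >= 2 samples.
#' @return Expression tibble of the same shape with every gene row at mean 0.
#' @export
center_genes <- function(x) {
  m <- expr_mat(x)
  if (ncol(m) < 2) {
    abort("cohort centering needs >= 2 samples; for single samples use stored-parameter standardisation (zscore_genes with `params`)")
  }
  expr_tbl(m - rowMeans(m))
}

#' Per-gene standard score (z = (x - mu) / sigma)
#'
#' In cohort mode (`params = NULL`) mu and sigma are estimated from the input
#' itself, with the population (n-denominator) standard deviation, so output
#' rows have mean 0 and sd 1 exactly. In stored mode the supplied parameters
#' (e.g. a model's training statistics) are applied unchanged.
#'
#' @param x Wide expression tibble (or genes x samples matrix).
#' @param params `NULL` for cohort mode, or a tibble with columns `gene`,
#'   `mu`, `sigma` for stored mode.
#' @return Standardised expression tibble; the parameters actually used are
#'   attached as attribute `norm_params` (retrieve with [norm_params()]).
#' @export
zscore_genes <- function(x, params = NULL) {
  m <- expr_mat(x)
  if (is.null(params)) {
    if (ncol(m) < 2) {
      abort("cohort-mode standardisation needs >= 2 samples; supply stored `params`")
    }
    mu <- rowMeans(m)
    sigma <- row_sd_pop(m)
    if (any(sigma == 0)) {
      abort(paste0("zero-variance gene(s) in cohort mode: ",
                   paste(rownames(m)[sigma == 0], collapse = ", ")))
    }
    used <- tibble::tibble(gene = rownames(m), mu = unname(mu),
                           sigma = unname(sigma), mode = "cohort")
  } else {
    if (!all(c("gene", "mu", "sigma") %in% names(params))) {
      abort("stored params must have columns gene, mu, sigma")
    }
    absent <- setdiff(rownames(m), params$gene)
    if (length(absent)) {
      abort(paste0("no stored parameters for gene(s): ", paste(absent, collapse = ", ")))
    }
    idx <- match(rownames(m), params$gene)
    mu <- params$mu[idx]
    sigma <- params$sigma[idx]
    if (any(sigma <= 0)) abort("stored sigma must be > 0 for every gene")
    used <- tibble::tibble(gene = rownames(m), mu = mu, sigma = sigma,
                           mode = "stored")
  }
  out <- expr_tbl((m - mu) / sigma)
  attr(out, "norm_params") <- used
  out
}

#' Retrieve the standardisation parameters attached by [zscore_genes()]
#' @param x Output of [zscore_genes()].
#' @return Tibble with columns `gene`, `mu`, `sigma`, `mode`.
#' @export
norm_params <- function(x) {
  p <- attr(x, "norm_params")
  if (is.null(p)) abort("no normalisation parameters attached")
  p
}

#' Write/read standardisation parameters as TSV
#' @param params Tibble with columns `gene`, `mu`, `sigma`.
#' @param path File path.
#' @return `path` (write) or the parameter tibble (read).
#' @export
write_norm_params <- function(params, path) {
  readr::write_tsv(params[c("gene", "mu", "sigma")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}
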