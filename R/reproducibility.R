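# Cross-platform reproducibility filtering.

#' Filter genes by cross-platform Pearson reproducibility
#'
#' Given the same specimens measured on two platforms, computes each gene's
#' Pearson correlation across samples between the platforms and eliminates
#' genes correlating below the threshold (strictly lower than the threshold
#' eliminates, so a gene at exactly the threshold is kept). Zero-variance
#' genes have no defined correlation and are eliminated with a recorded
#' reason.
#'
#' @param a,b Wide expression tibbles (or matrices) of the same specimens on
#'   two platforms; genes and samples are matched by name and must overlap in
#'   >= 3 shared samples.
#' @param threshold Pearson r retention threshold, default 0.65.
#' @return Tibble with one row per shared gene: `gene`, `r`, `retained`,
#'   `reason` (`NA` for retained genes). Retained genes are
#'   `dplyr::filter(out, retained)$gene`.
#' @export
correlation_reproducibility_filter <- function(a, b, threshold = 0.65) {
  ma <- expr_mat(a)
  mb <- expr_mat(b)
  samples <- intersect(colnames(ma), colnames(mb))
  if (length(samples) < 3) abort("need >= 3 shared samples to assess reproducibility")
  genes <- intersect(rownames(ma), rownames(mb))
  if (!length(genes)) abort("no shared genes between the two platforms")
  ma <- ma[genes, samples, drop = FALSE]
  mb <- mb[genes, samples, drop = FALSE]
  sda <- row_sd_pop(ma)
  sdb <- row_sd_pop(mb)
  r <- rep(NA_real_, length(genes))
  ok <- sda > 0 & sdb > 0
  if (any(ok)) {
    ca <- ma[ok, , drop = FALSE] - rowMeans(ma[ok, , drop = FALSE])
    cb <- mb[ok, , drop = FALSE] - rowMeans(mb[ok, , drop = FALSE])
    r[ok] <- rowSums(ca * cb) / (length(samples) * sda[ok] * sdb[ok])
  }
  retained <- !is.na(r) & r >= threshold
  reason <- dplyr::case_when(
    is.na(r) ~ "zero variance on one platform",
    r < threshold ~ paste0("r below ", threshold),
    TRUE ~ NA_character_
  )
  tibble::tibble(gene = genes, r = r, retained = retained, reason = reason)
}
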