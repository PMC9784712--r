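# Synthetic three-subtype cohorts with planted subtype-specific expression
# blocks, platform distortions, and CT-scale output. Every pipeline stage is
# testable against these cohorts without external data.

#' Default signed expression pattern of the 20 panel genes
#'
#' Encodes the subtype-specific blocks observed across cohorts: eight genes
#' up in proneural (BCAS1, GPR17, ERBB3, PDGFRA, SNAP91, DNM3, KLRC3, PFN2),
#' four up in mesenchymal (MET, FCGR2B, DAB2, PTPRC), six up in classical
#' (EGFR, SPRY2, VAV3, CDH4, NR2E1, NES), CHI3L1 down in proneural and CSPG5
#' down in mesenchymal.
#'
#' @return Tibble with columns `gene`, `CL`, `MES`, `PN`; entries in
#'   \{-1, 0, +1\} multiply the effect size for samples of that subtype.
#' @export
default_pattern <- function() {
  pn_up <- c("BCAS1", "GPR17", "ERBB3", "PDGFRA", "SNAP91", "DNM3", "KLRC3", "PFN2")
  mes_up <- c("MET", "FCGR2B", "DAB2", "PTPRC")
  cl_up <- c("EGFR", "SPRY2", "VAV3", "CDH4", "NR2E1", "NES")
  genes <- c(pn_up, mes_up, cl_up, "CHI3L1", "CSPG5")
  tb <- tibble::tibble(gene = genes, CL = 0, MES = 0, PN = 0)
  tb$PN[tb$gene %in% pn_up] <- 1
  tb$MES[tb$gene %in% mes_up] <- 1
  tb$CL[tb$gene %in% cl_up] <- 1
  tb$PN[tb$gene == "CHI3L1"] <- -1
  tb$MES[tb$gene == "CSPG5"] <- -1
  tb
}

#' The published five-gene panel
#' @return Character vector KLRC3, VAV3, EGFR, CSPG5, FCGR2B.
#' @export
five_gene_panel <- function() c("KLRC3", "VAV3", "EGFR", "CSPG5", "FCGR2B")

#' Generate a synthetic three-subtype cohort
#'
#' Draws log2 expression as `baseline(gene) + pattern(gene, subtype) * delta
#' + Normal(0, sigma)`. Per-gene baselines are drawn once from
#' Uniform(`baseline_range`) under the seed, so the whole cohort is
#' reproducible from the spec. Optional pattern-free noise genes (named
#' `NOISE01`, ...) can be appended for feature-selection experiments.
#' Default cohort sizes mirror a microarray development cohort
#' (CL 140, MES 151, PN 128).
#'
#' @param n_cl,n_mes,n_pn Samples per subtype (>= 0, not all zero).
#' @param pattern Signed pattern tibble (`gene`, `CL`, `MES`, `PN`);
#'   default [default_pattern()].
#' @param delta Effect size in log2 units (default 2).
#' @param sigma Noise standard deviation in log2 units (default 1).
#' @param n_noise_genes Pattern-free genes to append (default 0).
#' @param baseline_range Range of per-gene baseline means, log2 units
#'   (default 4-12).
#' @param seed Seed controlling the noise draw (and, by default, the
#'   baselines).
#' @param baseline_seed Seed for the per-gene baselines (defaults to `seed`).
#'   Cohorts meant to emulate repeated measurements on the same assay — e.g.
#'   a training cohort and a later test cohort for stored-parameter
#'   prediction — should share a `baseline_seed` so their genes sit on a
#'   common scale.
#' @return List with `expression` (wide tibble) and `labels` (tibble
#'   `sample`, `subtype`).
#' @export
generate_cohort <- function(n_cl = 140, n_mes = 151, n_pn = 128,
                            pattern = default_pattern(),
                            delta = 2, sigma = 1, n_noise_genes = 0,
                            baseline_range = c(4, 12), seed = 1,
                            baseline_seed = seed) {
  if (delta < 0 || sigma < 0) abort("delta and sigma must be >= 0")
  if (n_cl < 0 || n_mes < 0 || n_pn < 0) abort("sample counts must be >= 0")
  n <- n_cl + n_mes + n_pn
  if (n == 0) abort("at least one subtype must have samples")
  if (!all(c("gene", "CL", "MES", "PN") %in% names(pattern))) {
    abort("pattern must have columns gene, CL, MES, PN")
  }
  pat <- as.matrix(pattern[c("CL", "MES", "PN")])
  rownames(pat) <- pattern$gene
  if (n_noise_genes > 0) {
    noise_names <- sprintf("NOISE%02d", seq_len(n_noise_genes))
    pat <- rbind(pat, matrix(0, n_noise_genes, 3,
                             dimnames = list(noise_names, colnames(pat))))
  }
  genes <- rownames(pat)
  p <- length(genes)
  subtype <- rep(c("CL", "MES", "PN"), c(n_cl, n_mes, n_pn))
  samples <- sprintf("S%04d", seq_len(n))
  baseline <- withr::with_seed(baseline_seed,
                               runif(p, baseline_range[1], baseline_range[2]))
  means <- baseline + pat[, subtype, drop = FALSE] * delta
  m <- withr::with_seed(seed, means + matrix(rnorm(p * n, sd = sigma), p, n))
  dimnames(m) <- list(genes, samples)
  list(expression = expr_tbl(m),
       labels = tibble::tibble(sample = samples, subtype = subtype))
}

#' Re-measure a cohort on an emulated second platform
#'
#' Applies a per-gene affine transform plus Gaussian cross-platform noise:
#' `value' = shift + scale * value + Normal(0, noise_sd)`. Genes listed in
#' `low_repro_genes` instead receive noise calibrated to
#' `low_repro_factor` times their own observed standard deviation, which
#' drives their expected cross-platform Pearson correlation to
#' `1 / sqrt(1 + low_repro_factor^2)` (about 0.32 at the default factor 3,
#' well below a 0.65 reproducibility threshold).
#'
#' @param x Wide expression tibble (or genes x samples matrix).
#' @param shift,scale Affine parameters, scalars or per-gene vectors
#'   (scale > 0).
#' @param noise_sd Cross-platform noise sd, scalar or per-gene (>= 0).
#' @param low_repro_genes Genes to corrupt into low reproducibility.
#' @param low_repro_factor Noise-to-signal sd ratio for those genes
#'   (default 3).
#' @param seed Seed for the noise draw.
#' @return Expression tibble of the same shape.
#' @export
emulate_second_platform <- function(x, shift = 0, scale = 1, noise_sd = 0,
                                    low_repro_genes = character(),
                                    low_repro_factor = 3, seed = 1) {
  m <- expr_mat(x)
  p <- nrow(m)
  shift <- rep_len(shift, p)
  scale <- rep_len(scale, p)
  noise_sd <- rep_len(noise_sd, p)
  if (any(scale <= 0)) abort("platform scale must be > 0")
  if (any(noise_sd < 0)) abort("platform noise sd must be >= 0")
  unknown <- setdiff(low_repro_genes, rownames(m))
  if (length(unknown)) {
    abort(paste0("low_repro_genes absent from matrix: ", paste(unknown, collapse = ", ")))
  }
  lr <- rownames(m) %in% low_repro_genes
  noise_sd[lr] <- low_repro_factor * row_sd_pop(m)[lr]
  out <- withr::with_seed(seed, {
    shift + scale * m + matrix(rnorm(length(m)), p) * noise_sd
  })
  dimnames(out) <- dimnames(m)
  expr_tbl(out)
}

#' Emulate qPCR measurement of an expression matrix
#'
#' Inverts the delta-CT transform: each replicate CT is
#' `ref_level - value + Normal(0, replicate_sd)`, and the reference genes are
#' emitted at `ref_level` with the same replicate noise (the housekeeping
#' assumption: no subtype pattern). One extra log2 unit of expression lowers
#' CT by one cycle. With `replicate_sd = 0`,
#' `ct_to_log_expression(aggregate_ct(...))` recovers the input exactly up to
#' a per-sample additive constant, which [center_genes()] removes.
#'
#' @param x Wide expression tibble (or genes x samples matrix).
#' @param ref_level CT level of the reference genes (default 20 cycles).
#' @param replicate_sd Replicate noise sd in cycles (default 0.15).
#' @param replicates Replicate measurements per gene x sample (default 3).
#' @param ref_genes Names of the emitted reference genes.
#' @param seed Seed for the replicate noise.
#' @return Long tibble (`sample`, `gene`, `replicate`, `ct`) ready for
#'   [aggregate_ct()] or [write_ct_table()]. CT values falling outside
#'   (0, 45] are clipped with a warning.
#' @export
expression_to_ct <- function(x, ref_level = 20, replicate_sd = 0.15,
                             replicates = 3, ref_genes = REF_GENES,
                             seed = 1) {
  if (replicates < 1) abort("need >= 1 replicate")
  if (replicate_sd < 0) abort("replicate_sd must be >= 0")
  m <- expr_mat(x)
  if (any(rownames(m) %in% ref_genes)) {
    abort("input genes collide with the emitted reference gene names")
  }
  full <- rbind(m, matrix(0, length(ref_genes), ncol(m),
                          dimnames = list(ref_genes, colnames(m))))
  base_ct <- ref_level - full
  long <- tidyr::crossing(
    tibble::tibble(gene = rownames(full)),
    tibble::tibble(sample = colnames(full)),
    tibble::tibble(replicate = seq_len(replicates))
  )
  long <- long[c("sample", "gene", "replicate")]
  ct0 <- base_ct[cbind(match(long$gene, rownames(full)),
                       match(long$sample, colnames(full)))]
  ct <- withr::with_seed(seed, ct0 + rnorm(length(ct0), sd = replicate_sd))
  n_clip <- sum(ct <= 0 | ct > 45)
  if (n_clip > 0) {
    warn(paste0(n_clip, " CT value(s) outside (0, 45] were clipped"))
    ct <- pmin(pmax(ct, 1e-6), 45)
  }
  long$ct <- ct
  dplyr::arrange(long, .data$sample, .data$gene, .data$replicate)
}

#' Write a long-format CT table to TSV
#' @param ct Long tibble with columns `sample`, `gene`, `replicate`, `ct`
#'   (e.g. from [expression_to_ct()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  readr::write_tsv(ct, path, progress = FALSE)
  invisible(path)
}
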