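# Delimited-text IO for expression matrices, sample metadata and predictions.

# Sniff the delimiter from the header line: TSV by default, comma when the
# header contains commas and no tabs.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Read a log-expression matrix from delimited text
#'
#' Reads a TSV (comma auto-detected) matrix of log-scale expression values into
#' the package's wide tibble form: first column `gene`, one numeric column per
#' sample. Files may store genes in rows (header row = sample IDs) or samples
#' in rows (header row = gene symbols); the result is always genes x samples.
#'
#' @param path Path to a delimited text file with one header row and one
#'   identifier column.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return A tibble with columns `gene`, `<sample1>`, `<sample2>`, ...
#'   Gene symbols and sample IDs are checked for uniqueness; any non-numeric
#'   expression cell is an error naming its location.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tS1\tS2", "EGFR\t8.1\t7.9"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) abort("expression file needs an identifier column plus data columns")
  ids <- as.character(raw[[1]])
  vals <- raw[-1]
  num <- lapply(vals, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(vals[[j]]) &
                   !(trimws(vals[[j]]) %in% c("NA", "")))
    if (length(bad)) {
      abort(paste0("non-numeric value '", vals[[j]][bad[1]], "' at row ", bad[1],
                   " (", ids[bad[1]], "), column ", names(vals)[j]))
    }
  }
  m <- do.call(cbind, num)
  colnames(m) <- names(vals)
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    abort(paste0("duplicate gene symbols: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    abort(paste0("duplicate sample IDs: ", paste(dup, collapse = ", ")))
  }
  expr_tbl(m)
}

#' Write an expression matrix to TSV
#'
#' Genes in rows, header row of sample IDs. Values are written at full
#' precision so a write/read round trip reproduces them exactly.
#'
#' @param x Wide expression tibble (or genes x samples matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  m <- expr_mat(x)
  tbl <- expr_tbl(m)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a delimited file with at least a `sample` column; recognised
#' optional columns are `subtype` (CL/MES/PN/Neural/unknown), `sample_type`
#' (primary/recurrent/secondary) and `prior_treatment` (logical). Missing
#' optional columns are filled with permissive defaults so that the
#' corresponding [filter_cases()] criteria pass vacuously.
#'
#' @param path Path to a TSV/CSV file.
#' @return Tibble with columns `sample`, `subtype`, `sample_type`,
#'   `prior_treatment`, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- sniff_delim(path)
  meta <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                            progress = FALSE)
  if (!"sample" %in% names(meta)) abort("metadata file must have a `sample` column")
  meta$sample <- as.character(meta$sample)
  if (anyDuplicated(meta$sample)) {
    abort(paste0("duplicate metadata records for: ",
                 paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", ")))
  }
  if (!"subtype" %in% names(meta)) meta$subtype <- "unknown"
  if (!"sample_type" %in% names(meta)) meta$sample_type <- "primary"
  if (!"prior_treatment" %in% names(meta)) meta$prior_treatment <- FALSE
  meta$prior_treatment <- as.logical(meta$prior_treatment)
  ok <- c(subtype_levels(), "Neural", "unknown")
  bad <- setdiff(unique(meta$subtype), ok)
  if (length(bad)) {
    abort(paste0("subtype labels outside {", paste(ok, collapse = ", "), "}: ",
                 paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(meta[c("sample", "subtype", "sample_type", "prior_treatment",
                           setdiff(names(meta), c("sample", "subtype", "sample_type",
                                                  "prior_treatment")))])
}

#' Write per-sample subtype predictions to TSV
#'
#' @param predictions Prediction tibble from [predict_cohort()] (columns
#'   `sample`, `subtype`, `p_CL`, `p_MES`, `p_PN`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("sample", "subtype", "p_CL", "p_MES", "p_PN")
  if (!all(need %in% names(predictions))) {
    abort(paste0("prediction table must have columns: ", paste(need, collapse = ", ")))
  }
  readr::write_tsv(predictions[need], path, progress = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#' @param path Path to the predictions file.
#' @return Prediction tibble.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), subtype = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
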