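# Internal helpers shared across modules.

# Convert a wide expression tibble (first column = gene symbols, remaining
# columns = samples) to a genes x samples numeric matrix with dimnames.
expr_mat <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("expression matrix must carry gene rownames and sample colnames")
    }
    storage.mode(x) <- "double"
    return(x)
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2) abort("expression table needs a gene column plus >=1 sample column")
  genes <- as.character(x[[1]])
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(paste0("duplicate gene symbols: ", paste(dup, collapse = ", ")))
  }
  vals <- x[-1]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric sample columns: ", paste(names(vals)[bad], collapse = ", ")))
  }
  if (anyDuplicated(names(vals))) {
    abort(paste0("duplicate sample IDs: ",
                 paste(unique(names(vals)[duplicated(names(vals))]), collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

# Inverse of expr_mat(): matrix -> wide tibble with a `gene` first column.
expr_tbl <- function(m) {
  tibble::as_tibble(cbind(tibble::tibble(gene = rownames(m)),
                          tibble::as_tibble(m, .name_repair = "minimal")))
}

# Normalise a label input (tibble with sample/subtype columns, or a named or
# plain character vector) to a factor aligned with `samples`, levels CL/MES/PN.
align_labels <- function(labels, samples, allow_extra_levels = FALSE) {
  if (is.data.frame(labels)) {
    if (!all(c("sample", "subtype") %in% names(labels))) {
      abort("label table must have columns `sample` and `subtype`")
    }
    v <- setNames(as.character(labels$subtype), as.character(labels$sample))
  } else if (!is.null(names(labels))) {
    v <- setNames(as.character(labels), names(labels))
  } else {
    if (length(labels) != length(samples)) {
      abort("unnamed label vector must match the number of samples")
    }
    v <- setNames(as.character(labels), samples)
  }
  missing <- setdiff(samples, names(v))
  if (length(missing)) {
    abort(paste0("samples without a subtype label: ", paste(missing, collapse = ", ")))
  }
  v <- v[samples]
  lev <- subtype_levels()
  bad <- setdiff(unique(v), lev)
  if (length(bad) && !allow_extra_levels) {
    abort(paste0("subtype labels outside {CL, MES, PN}: ", paste(bad, collapse = ", ")))
  }
  factor(v, levels = if (allow_extra_levels) unique(c(lev, bad)) else lev)
}

# Stratified fold assignment: within each class, samples are shuffled and dealt
# round-robin into `k` folds, so per-fold class counts differ from exact
# proportionality by at most one.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (k < 2) abort("need at least 2 folds")
  cnt <- table(y)
  if (any(cnt < k)) {
    abort(paste0("class ", names(cnt)[which.min(cnt)], " has ", min(cnt),
                 " samples, fewer than ", k, " folds; reduce `folds`"))
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Population-convention per-row standard deviation (n denominator).
row_sd_pop <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

# Equal-frequency discretisation, right-closed bins. Input with at most
# `bins` distinct values is already discrete and keeps its own categories
# (quantile breaks on skewed discrete data would otherwise collapse levels);
# constant vectors collapse to a single bin.
discretize_ef <- function(x, bins = 4) {
  u <- sort(unique(x))
  if (length(u) <= bins) return(match(x, u))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, right = TRUE, labels = FALSE)
}

# Shannon entropy (bits) of a count table / vector of counts.
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Mutual information (bits) between two discrete vectors.
mutual_info <- function(a, b) {
  entropy_bits(table(a)) + entropy_bits(table(b)) - entropy_bits(table(a, b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
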