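# Evaluation battery: confusion/accuracy, one-vs-rest ROC/AUC, MDS centroid
# distances, bi-cluster ordering, subtype proportion z test.

#' Confusion matrix and accuracy
#'
#' @param reference,predicted Aligned subtype label vectors (values in CL,
#'   MES, PN); `predicted` may also be a prediction tibble from
#'   [predict_cohort()], in which case its `subtype` column is used.
#' @return A `subtype_eval`: 3x3 `confusion` matrix (rows = reference,
#'   columns = predicted), overall `accuracy` (trace / total), and a
#'   `per_class` tibble (diagonal / row sum; `NA` for a class absent from the
#'   reference).
#' @export
confusion_and_accuracy <- function(reference, predicted) {
  if (is.data.frame(predicted)) predicted <- predicted$subtype
  if (is.data.frame(reference)) reference <- reference$subtype
  lev <- subtype_levels()
  for (v in list(reference, predicted)) {
    bad <- setdiff(unique(as.character(v)), lev)
    if (length(bad)) {
      abort(paste0("labels outside {CL, MES, PN}: ", paste(bad, collapse = ", ")))
    }
  }
  if (length(reference) != length(predicted)) {
    abort("reference and predicted must have equal length")
  }
  ref <- factor(as.character(reference), levels = lev)
  prd <- factor(as.character(predicted), levels = lev)
  confusion <- table(reference = ref, predicted = prd)
  confusion <- matrix(as.integer(confusion), 3, 3, dimnames = dimnames(confusion))
  rs <- rowSums(confusion)
  per_class <- tibble::tibble(
    subtype = lev,
    n = as.integer(rs),
    accuracy = unname(ifelse(rs > 0, diag(confusion) / rs, NA_real_))
  )
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / length(ref),
                 per_class = per_class),
            class = "subtype_eval")
}

#' @export
print.subtype_eval <- function(x, ...) {
  cat("<subtype_eval> accuracy ", sprintf("%.3f", x$accuracy), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

# Trapezoidal AUC over all score thresholds (ties grouped, so it equals the
# pairwise P(s_pos > s_neg) + 0.5 P(equal) estimator). NA when either class
# is empty.
auc_trapezoid <- function(score, positive) {
  P <- sum(positive)
  N <- sum(!positive)
  if (P == 0 || N == 0) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  p <- positive[o]
  idx <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(p)[idx] / P)
  fpr <- c(0, cumsum(!p)[idx] / N)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

roc_points <- function(score, positive) {
  P <- sum(positive)
  N <- sum(!positive)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  p <- positive[o]
  idx <- cumsum(rle(s)$lengths)
  tibble::tibble(threshold = c(Inf, s[idx]),
                 fpr = c(0, cumsum(!p)[idx] / N),
                 tpr = c(0, cumsum(p)[idx] / P))
}

#' One-vs-rest ROC curves and AUC per subtype
#'
#' For each subtype, samples of that subtype are the positives and the pooled
#' other two subtypes the negatives; the subtype's predicted probability is
#' the score. AUC is the trapezoidal area over all score thresholds (with
#' tied scores grouped, this equals the Mann-Whitney pairwise estimator).
#'
#' @param probabilities Prediction tibble with columns `p_CL`, `p_MES`,
#'   `p_PN` (e.g. from [predict_cohort()]), or a samples x 3 matrix in class
#'   order.
#' @param reference Reference subtype labels aligned with the rows.
#' @return A `subtype_roc`: `auc` tibble (`subtype`, `auc`; `NA` when a class
#'   has no positives or no negatives) and `curves` tibble (`subtype`,
#'   `threshold`, `fpr`, `tpr`).
#' @export
roc_one_vs_rest <- function(probabilities, reference) {
  lev <- subtype_levels()
  if (is.data.frame(probabilities)) {
    need <- paste0("p_", lev)
    if (!all(need %in% names(probabilities))) {
      abort(paste0("probability table must have columns: ", paste(need, collapse = ", ")))
    }
    pm <- as.matrix(probabilities[need])
  } else {
    pm <- as.matrix(probabilities)
    if (ncol(pm) != 3) abort("probability matrix must have 3 columns (CL, MES, PN)")
  }
  if (is.data.frame(reference)) reference <- reference$subtype
  if (length(reference) != nrow(pm)) {
    abort("reference labels must align with probability rows")
  }
  ref <- as.character(reference)
  auc <- tibble::tibble(subtype = lev, auc = NA_real_)
  curves <- list()
  for (i in seq_along(lev)) {
    pos <- ref == lev[i]
    if (!any(pos) || all(pos)) next
    auc$auc[i] <- auc_trapezoid(pm[, i], pos)
    curves[[i]] <- dplyr::mutate(roc_points(pm[, i], pos),
                                 subtype = lev[i], .before = 1)
  }
  structure(list(auc = auc, curves = dplyr::bind_rows(curves)),
            class = "subtype_roc")
}

#' @export
print.subtype_roc <- function(x, ...) {
  cat("<subtype_roc> one-vs-rest AUC\n")
  print(x$auc)
  invisible(x)
}

#' Metric MDS embedding with subtype centroid distances
#'
#' Embeds samples in two dimensions from their pairwise Euclidean distances
#' (classical Torgerson scaling refined by Sammon stress minimisation, a
#' deterministic procedure), then returns the per-subtype centroids of the
#' embedded points and their pairwise Euclidean distances. The input should
#' be standardised expression (see [zscore_genes()]).
#'
#' @param x Wide expression tibble (or genes x samples matrix), >= 3 samples.
#' @param labels Subtype labels aligned with the samples.
#' @return A `subtype_mds`: `coords` tibble (`sample`, `dim1`, `dim2`,
#'   `subtype`), symmetric zero-diagonal `centroid_dist` matrix, and the
#'   final `stress`.
#' @export
mds_centroid_distances <- function(x, labels) {
  m <- expr_mat(x)
  n <- ncol(m)
  if (n < 2) abort("MDS in 2 dimensions needs at least as many samples as dimensions")
  y <- align_labels(labels, colnames(m))
  d <- dist(t(m))
  init <- cmdscale(d, k = min(2, n - 1))
  if (ncol(init) < 2) init <- cbind(init, rep(0, nrow(init)))
  # two points: the classical solution is already exact, nothing to refine
  ref <- if (n == 2) list(points = init, stress = 0) else tryCatch(
    MASS::sammon(d, y = init, trace = FALSE),
    error = function(e) NULL
  )
  if (!is.null(ref)) {
    coords <- ref$points
    stress <- ref$stress
  } else {
    coords <- init
    dm <- as.matrix(d)
    dhat <- as.matrix(dist(coords))
    off <- upper.tri(dm) & dm > 0
    stress <- sum((dm[off] - dhat[off])^2 / dm[off]) / sum(dm[off])
  }
  lev <- levels(droplevels(y))
  cent <- vapply(lev, function(cl) colMeans(coords[y == cl, , drop = FALSE]),
                 numeric(2))
  centroid_dist <- as.matrix(dist(t(cent)))
  dimnames(centroid_dist) <- list(lev, lev)
  structure(list(
    coords = tibble::tibble(sample = colnames(m),
                            dim1 = coords[, 1], dim2 = coords[, 2],
                            subtype = as.character(y)),
    centroid_dist = centroid_dist,
    stress = stress
  ), class = "subtype_mds")
}

#' Hierarchical bi-cluster ordering for heatmaps
#'
#' Clusters genes and samples independently (Euclidean distance, average
#' linkage) and returns the two leaf orders. Deterministic given the input.
#'
#' @param x Wide expression tibble (or genes x samples matrix).
#' @return List with `row_order`/`col_order` (integer permutations),
#'   `row_labels`/`col_labels` (genes and samples in heatmap order).
#' @export
bicluster_order <- function(x) {
  m <- expr_mat(x)
  row_order <- if (nrow(m) > 1) hclust(dist(m), method = "average")$order else 1L
  col_order <- if (ncol(m) > 1) hclust(dist(t(m)), method = "average")$order else 1L
  list(row_order = row_order, col_order = col_order,
       row_labels = rownames(m)[row_order], col_labels = colnames(m)[col_order])
}

#' Two-proportion pooled z test
#'
#' Compares the proportion k1/n1 against k2/n2 with the pooled-variance
#' two-proportion z statistic (no continuity correction); the two-sided p
#' comes from the normal distribution. Used to compare subtype proportions
#' between cohorts.
#'
#' @param k1,n1 Successes and total in the first group.
#' @param k2,n2 Successes and total in the second group.
#' @return One-row tibble: `p1`, `p2`, `z`, `p_value`. When the pooled
#'   proportion is 0 or 1 the statistic is undefined and `z`/`p_value` are
#'   `NA`.
#' @export
#' @examples
#' proportion_ztest(30, 100, 10, 100)  # z ~ 3.54
proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    abort("need 0 <= k <= n and n > 0 in both groups")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    return(tibble::tibble(p1 = p1, p2 = p2, z = NA_real_, p_value = NA_real_))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  tibble::tibble(p1 = p1, p2 = p2, z = z, p_value = 2 * pnorm(-abs(z)))
}
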