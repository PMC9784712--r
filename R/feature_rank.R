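# Per-gene feature ranking: ANOVA F, ReliefF, Gini decrease, gain ratio,
# FCBF symmetrical uncertainty, mRMR. All methods also report a
# mean-normalised score (raw / method mean) so that methods with different
# units can be summed into a cumulative score.

#' Score genes for subtype discrimination
#'
#' Computes one or several per-gene ranking scores:
#' \describe{
#'   \item{anova}{one-way F statistic of expression across subtypes. Genes
#'     with zero within-group variance have an infinite F; these are capped at
#'     10x the largest finite F in the cohort (or `f_cap` if none is finite)
#'     to keep mean-normalisation defined.}
#'   \item{relieff}{ReliefF weight: k-nearest hits/misses (Manhattan distance
#'     on min-max scaled features), all instances used, miss contributions
#'     weighted by class prior.}
#'   \item{gini}{Gini impurity decrease of the class given the discretised
#'     gene.}
#'   \item{gain_ratio}{information gain divided by the discretised gene's own
#'     entropy.}
#'   \item{fcbf}{symmetrical uncertainty 2*IG / (H(gene) + H(class)) on the
#'     discretised gene, the relevance score of the fast correlation-based
#'     filter.}
#'   \item{mrmr}{greedy minimum-redundancy maximum-relevance selection
#'     (additive MID variant: MI with the class minus mean MI with already
#'     selected genes); the selection order is converted to a score of
#'     (number of genes - selection rank), so earlier-selected genes score
#'     higher.}
#' }
#' Discretisation for the information-theoretic methods is equal-frequency
#' with `bins` right-closed intervals.
#'
#' @param x Wide expression tibble (or genes x samples matrix).
#' @param labels Subtype labels: tibble (`sample`, `subtype`), named vector,
#'   or vector aligned with the matrix columns.
#' @param methods Character vector of methods to run (default: all six).
#' @param bins Number of equal-frequency bins for discretisation (default 4).
#' @param relieff_k Number of nearest hits/misses for ReliefF (default 10).
#' @param f_cap Cap used for infinite F statistics when no finite F exists
#'   (default 1e6).
#' @return A `feature_ranking` tibble with columns `gene`, `method`, `score`,
#'   `score_norm` (one row per gene per method). Normalised scores average to
#'   1 over the scored genes for each method (when the method's mean raw
#'   score is positive).
#' @export
score_features <- function(x, labels,
                           methods = c("anova", "relieff", "gini",
                                       "gain_ratio", "fcbf", "mrmr"),
                           bins = 4, relieff_k = 10, f_cap = 1e6) {
  known <- c("anova", "relieff", "gini", "gain_ratio", "fcbf", "mrmr")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    abort(paste0("unknown ranking method(s): ", paste(bad, collapse = ", ")))
  }
  m <- expr_mat(x)
  y <- droplevels(align_labels(labels, colnames(m)))
  if (nlevels(y) < 2) abort("need >= 2 classes to score features")

  disc <- NULL
  need_disc <- any(methods %in% c("gini", "gain_ratio", "fcbf", "mrmr"))
  if (need_disc) {
    disc <- t(apply(m, 1, discretize_ef, bins = bins))
  }
  res <- purrr::map(methods, function(method) {
    raw <- switch(method,
      anova = anova_f_scores(m, y, f_cap = f_cap),
      relieff = relieff_scores(m, y, k = relieff_k),
      gini = apply(disc, 1, gini_decrease, y = y),
      gain_ratio = apply(disc, 1, gain_ratio_score, y = y),
      fcbf = apply(disc, 1, symmetrical_uncertainty, y = y),
      mrmr = mrmr_scores(disc, y)
    )
    mu <- mean(raw)
    norm <- if (is.finite(mu) && mu > .Machine$double.eps) raw / mu else rep(0, length(raw))
    tibble::tibble(gene = rownames(m), method = method,
                   score = unname(raw), score_norm = unname(norm))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("feature_ranking", class(out))
  out
}

# One-way ANOVA F per gene, vectorised over genes. Zero within-group variance
# with nonzero between-group variance gives +Inf, capped afterwards.
anova_f_scores <- function(m, y, f_cap = 1e6) {
  cnt <- table(y)
  if (any(cnt < 2)) {
    abort(paste0("ANOVA needs >= 2 samples per class; class ",
                 names(cnt)[which.min(cnt)], " has ", min(cnt)))
  }
  n <- ncol(m)
  k <- nlevels(y)
  grand <- rowMeans(m)
  cm <- vapply(levels(y), function(cl) rowMeans(m[, y == cl, drop = FALSE]),
               numeric(nrow(m)))
  ssb <- rowSums(sweep((cm - grand)^2, 2, as.numeric(cnt), "*"))
  sst <- rowSums((m - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb == 0] <- 0
  if (any(!is.finite(f))) {
    finite_max <- suppressWarnings(max(f[is.finite(f)], 0))
    f[!is.finite(f)] <- if (finite_max > 0) 10 * finite_max else f_cap
  }
  setNames(f, rownames(m))
}

# ReliefF weights. Features are min-max scaled, distances are Manhattan, all
# instances contribute, k nearest hits and k nearest misses per other class,
# miss terms weighted P(class) / (1 - P(own class)).
relieff_scores <- function(m, y, k = 10) {
  X <- t(m)
  n <- nrow(X)
  p <- ncol(X)
  rng_min <- apply(X, 2, min)
  den <- apply(X, 2, max) - rng_min
  den[den == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng_min), 2, den, "/")
  D <- as.matrix(dist(Xs, method = "manhattan"))
  prior <- as.numeric(table(y)) / n
  names(prior) <- levels(y)
  W <- numeric(p)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    hits <- which(y == y[i])
    hits <- hits[hits != i]
    if (length(hits)) {
      kh <- min(k, length(hits))
      nh <- hits[order(D[i, hits])][seq_len(kh)]
      W <- W - colMeans(abs(sweep(Xs[nh, , drop = FALSE], 2, Xs[i, ])))
    }
    for (cl in setdiff(levels(y), ci)) {
      miss <- which(y == cl)
      if (!length(miss)) next
      km <- min(k, length(miss))
      nm <- miss[order(D[i, miss])][seq_len(km)]
      wgt <- prior[cl] / (1 - prior[ci])
      W <- W + wgt * colMeans(abs(sweep(Xs[nm, , drop = FALSE], 2, Xs[i, ])))
    }
  }
  setNames(W / n, rownames(m))
}

gini_impurity <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

# Gini impurity decrease of the class distribution attributable to a
# discretised feature.
gini_decrease <- function(xd, y) {
  total <- gini_impurity(table(y))
  tab <- table(xd, y)
  pv <- rowSums(tab) / sum(tab)
  child <- sum(pv * apply(tab, 1, gini_impurity))
  total - child
}

info_gain <- function(xd, y) {
  entropy_bits(table(y)) - (entropy_bits(table(xd, y)) - entropy_bits(table(xd)))
}

gain_ratio_score <- function(xd, y) {
  hx <- entropy_bits(table(xd))
  if (hx == 0) return(0)
  info_gain(xd, y) / hx
}

symmetrical_uncertainty <- function(xd, y) {
  hx <- entropy_bits(table(xd))
  hy <- entropy_bits(table(y))
  if (hx + hy == 0) return(0)
  2 * info_gain(xd, y) / (hx + hy)
}

# Greedy mRMR (MID variant) over discretised genes; returns scores mapping
# the selection order to (p - rank), earlier-selected genes scoring higher.
mrmr_scores <- function(disc, y) {
  p <- nrow(disc)
  genes <- rownames(disc)
  rel <- apply(disc, 1, mutual_info, b = y)
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)  # sum of MI with already-selected genes
  order_out <- integer(p)
  for (step in seq_len(p)) {
    crit <- if (length(selected) == 0) rel[remaining] else
      rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(crit)]
    order_out[step] <- pick
    remaining <- setdiff(remaining, pick)
    if (length(remaining)) {
      mi_new <- vapply(remaining, function(j) mutual_info(disc[pick, ], disc[j, ]),
                       numeric(1))
      red_sum[remaining] <- red_sum[remaining] + mi_new
    }
    selected <- c(selected, pick)
  }
  scores <- numeric(p)
  scores[order_out] <- p - seq_len(p)
  setNames(scores, genes)
}
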