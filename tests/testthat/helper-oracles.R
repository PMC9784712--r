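# Independent brute-force oracles used to cross-check the package's
# information-theoretic scores and AUC. Deliberately written as plain loops
# over contingency tables so they share no code with the implementation.

oracle_entropy <- function(x) {
  h <- 0
  for (v in unique(x)) {
    p <- sum(x == v) / length(x)
    h <- h - p * log2(p)
  }
  h
}

oracle_cond_entropy <- function(y, x) {
  h <- 0
  for (v in unique(x)) {
    idx <- x == v
    h <- h + sum(idx) / length(x) * oracle_entropy(y[idx])
  }
  h
}

oracle_info_gain <- function(xd, y) oracle_entropy(y) - oracle_cond_entropy(y, xd)

oracle_mutual_info <- function(a, b) oracle_info_gain(a, b)

oracle_gain_ratio <- function(xd, y) {
  hx <- oracle_entropy(xd)
  if (hx == 0) return(0)
  oracle_info_gain(xd, y) / hx
}

oracle_su <- function(xd, y) {
  hx <- oracle_entropy(xd)
  hy <- oracle_entropy(y)
  if (hx + hy == 0) return(0)
  2 * oracle_info_gain(xd, y) / (hx + hy)
}

oracle_gini <- function(x) {
  g <- 1
  for (v in unique(x)) g <- g - (sum(x == v) / length(x))^2
  g
}

oracle_gini_decrease <- function(xd, y) {
  g <- oracle_gini(y)
  for (v in unique(xd)) {
    idx <- xd == v
    g <- g - sum(idx) / length(xd) * oracle_gini(y[idx])
  }
  g
}

# Greedy mRMR (MID) selection order computed by brute force over a matrix of
# discretised genes (rows) and a label vector.
oracle_mrmr_order <- function(disc, y) {
  p <- nrow(disc)
  remaining <- seq_len(p)
  selected <- integer(0)
  while (length(remaining)) {
    crit <- sapply(remaining, function(j) {
      rel <- oracle_mutual_info(disc[j, ], y)
      if (!length(selected)) return(rel)
      red <- mean(sapply(selected, function(s) oracle_mutual_info(disc[j, ], disc[s, ])))
      rel - red
    })
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# Pairwise Mann-Whitney AUC estimator: P(score_pos > score_neg) + 0.5 P(equal).
oracle_auc_pairwise <- function(score, positive) {
  sp <- score[positive]
  sn <- score[!positive]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small wide expression tibble from a plain matrix definition.
make_expr <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  tibble::as_tibble(cbind(tibble::tibble(gene = genes),
                          tibble::as_tibble(as.data.frame(m))))
}

label_tbl <- function(samples, subtypes) {
  tibble::tibble(sample = samples, subtype = subtypes)
}
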