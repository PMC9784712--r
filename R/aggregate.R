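# Cumulative aggregation of ranking methods and the exhaustive fixed-size
# panel search.

#' Aggregate feature rankings into a cumulative score and top-k panel
#'
#' Sums the mean-normalised scores of each method per gene; the genes with the
#' highest cumulative values form the panel. Ties are broken by the higher
#' ANOVA raw score (when the anova method is present), then by gene symbol.
#'
#' @param rankings A `feature_ranking` tibble from [score_features()] (one or
#'   several methods row-bound together).
#' @param k Panel size (default 20).
#' @return A `gene_ranking` tibble with columns `gene`, `cumulative`, `rank`,
#'   `selected`, sorted by rank; the top-k gene panel is attached as attribute
#'   `panel` (retrieve with [panel_genes()]).
#' @export
aggregate_rankings <- function(rankings, k = 20) {
  if (is.null(rankings) || !nrow(rankings)) abort("empty rankings")
  need <- c("gene", "method", "score", "score_norm")
  if (!all(need %in% names(rankings))) {
    abort(paste0("rankings must have columns: ", paste(need, collapse = ", ")))
  }
  per_method <- split(rankings$gene, rankings$method)
  universe <- sort(unique(rankings$gene))
  same <- vapply(per_method, function(g) identical(sort(g), universe), logical(1))
  if (!all(same)) abort("all ranking methods must cover the same gene universe")
  if (k > length(universe)) abort("k exceeds the number of scored genes")

  anova_scores <- rankings |>
    dplyr::filter(.data$method == "anova") |>
    dplyr::select("gene", anova_score = "score")
  out <- rankings |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cumulative = sum(.data$score_norm), .groups = "drop") |>
    dplyr::left_join(anova_scores, by = "gene") |>
    dplyr::mutate(anova_score = dplyr::coalesce(.data$anova_score, 0)) |>
    dplyr::arrange(dplyr::desc(.data$cumulative), dplyr::desc(.data$anova_score),
                   .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number(), selected = .data$rank <= k) |>
    dplyr::select("gene", "cumulative", "rank", "selected")
  attr(out, "panel") <- out$gene[seq_len(k)]
  attr(out, "provenance") <- "top_k"
  class(out) <- c("gene_ranking", class(out))
  out
}

#' Extract the gene panel carried by a ranking or search result
#'
#' @param x A `gene_ranking` ([aggregate_rankings()]), a `panel_search`
#'   ([search_best_panel()]), or a plain character vector of gene symbols
#'   (returned as-is, after a uniqueness check).
#' @return Character vector of panel genes.
#' @export
panel_genes <- function(x) {
  if (is.character(x)) {
    if (anyDuplicated(x)) abort("panel genes must be unique")
    return(x)
  }
  p <- attr(x, "panel")
  if (is.null(p)) abort("no panel attached to this object")
  p
}

#' Exhaustive search for the best fixed-size gene panel
#'
#' Evaluates every combination of `panel_size` genes from `candidates` by
#' stratified cross-validated accuracy and returns the best one. Within each
#' training fold, standardisation parameters are re-estimated and applied to
#' the held-out fold. Accuracy ties are broken by the higher mean one-vs-rest
#' AUC of the pooled out-of-fold scores, then by gene symbols.
#'
#' The default learner `"lsq"` is a ridge-stabilised least-squares indicator
#' discriminant: class-indicator columns are regressed on the panel genes and
#' a sample is assigned to the class with the largest fitted score. Its linear
#' decision boundaries track those of the logistic model at a small fraction
#' of the cost, which is what makes the exhaustive search (e.g. C(20,5) =
#' 15,504 combinations, each cross-validated) practical. `"logreg_l1"` and
#' `"linear_svm"` evaluate the full classifiers instead and are intended for
#' small candidate pools.
#'
#' @param x Wide expression tibble (or genes x samples matrix).
#' @param labels Subtype labels (see [score_features()]).
#' @param candidates Candidate gene pool: character vector or an object with
#'   a panel attribute (e.g. the top-20 from [aggregate_rankings()]).
#' @param panel_size Panel size to search (default 5).
#' @param cv_folds Stratified CV folds (default 10).
#' @param learner `"lsq"` (default), `"logreg_l1"` or `"linear_svm"`.
#' @param reg_strength Regularisation strength for the full learners.
#' @param seed Seed for the fold assignment.
#' @param max_combinations Guard on the search-space size (default 1e6).
#' @return A `panel_search` tibble with one row per combination (`panel`
#'   comma-joined, `accuracy`, `mean_auc` for the top ties, `rank`), best
#'   first; the winning panel is attached as attribute `panel`.
#' @export
search_best_panel <- function(x, labels, candidates, panel_size = 5,
                              cv_folds = 10,
                              learner = c("lsq", "logreg_l1", "linear_svm"),
                              reg_strength = 1, seed = 1,
                              max_combinations = 1e6) {
  learner <- match.arg(learner)
  candidates <- panel_genes(candidates)
  m <- expr_mat(x)
  absent <- setdiff(candidates, rownames(m))
  if (length(absent)) {
    abort(paste0("candidate genes absent from matrix: ", paste(absent, collapse = ", ")))
  }
  if (panel_size > length(candidates)) {
    abort("panel_size exceeds the number of candidate genes")
  }
  n_comb <- choose(length(candidates), panel_size)
  if (n_comb > max_combinations) {
    abort(paste0("search space has ", format(n_comb, big.mark = ","),
                 " combinations (cap ", format(max_combinations, big.mark = ","),
                 "); reduce the candidate pool or use a heuristic (e.g. rank-based) pre-selection"))
  }
  y <- align_labels(labels, colnames(m))
  if (any(table(y) == 0)) abort("all three subtypes must be present")
  fold <- stratified_folds(y, cv_folds, seed)
  combos <- combn(length(candidates), panel_size)
  X <- t(m[candidates, , drop = FALSE])  # samples x candidates

  if (learner == "lsq") {
    acc <- lsq_search_accuracy(X, y, fold, combos)
  } else {
    acc <- apply(combos, 2, function(ci) {
      cv <- cross_validate(m[candidates[ci], , drop = FALSE], y,
                           panel = candidates[ci], learner = learner,
                           folds = cv_folds, reg_strength = reg_strength,
                           seed = seed)
      cv$accuracy
    })
  }

  panels <- apply(combos, 2, function(ci) paste(candidates[ci], collapse = ","))
  out <- tibble::tibble(panel = panels, accuracy = acc, mean_auc = NA_real_)

  best_acc <- max(acc)
  tied <- which(acc >= best_acc - 1e-12)
  if (length(tied) > 1) {
    for (j in tied) {
      scores <- pooled_oof_scores(X, y, fold, combos[, j], learner, reg_strength)
      out$mean_auc[j] <- mean(vapply(seq_len(nlevels(y)), function(ki) {
        auc_trapezoid(scores[, ki], y == levels(y)[ki])
      }, numeric(1)), na.rm = TRUE)
    }
  }
  ord <- order(-out$accuracy, -dplyr::coalesce(out$mean_auc, -Inf), out$panel)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "panel") <- strsplit(out$panel[1], ",")[[1]]
  attr(out, "provenance") <- "searched"
  attr(out, "seed") <- seed
  class(out) <- c("panel_search", class(out))
  out
}

# Batched least-squares indicator evaluation of all combinations. Per fold,
# the Gram matrix of the (intercept-augmented, fold-standardised) candidate
# matrix is precomputed once; each combination then costs one small solve.
lsq_search_accuracy <- function(X, y, fold, combos) {
  k <- max(fold)
  n <- nrow(X)
  K <- nlevels(y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  n_comb <- ncol(combos)
  correct <- numeric(n_comb)
  d <- nrow(combos) + 1L
  ridge <- diag(1e-8, d)
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- sqrt(colMeans(sweep(X[tr, , drop = FALSE], 2, mu)^2))
    sg[sg == 0] <- 1
    Xtr <- cbind(1, sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/"))
    Xte <- cbind(1, sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/"))
    G <- crossprod(Xtr)
    H <- crossprod(Xtr, Y[tr, , drop = FALSE])
    yte <- as.integer(y[!tr])
    for (j in seq_len(n_comb)) {
      c1 <- c(1L, combos[, j] + 1L)
      B <- solve(G[c1, c1] + ridge, H[c1, , drop = FALSE])
      P <- Xte[, c1, drop = FALSE] %*% B
      correct[j] <- correct[j] + sum(max.col(P, ties.method = "first") == yte)
    }
  }
  correct / n
}

# Pooled out-of-fold class scores for one combination (used for AUC
# tie-breaking and shared by all learners).
pooled_oof_scores <- function(X, y, fold, ci, learner, reg_strength) {
  n <- nrow(X)
  K <- nlevels(y)
  scores <- matrix(NA_real_, n, K)
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    mu <- colMeans(X[tr, ci, drop = FALSE])
    sg <- sqrt(colMeans(sweep(X[tr, ci, drop = FALSE], 2, mu)^2))
    sg[sg == 0] <- 1
    Ztr <- t(sweep(sweep(X[tr, ci, drop = FALSE], 2, mu), 2, sg, "/"))
    Zte <- t(sweep(sweep(X[!tr, ci, drop = FALSE], 2, mu), 2, sg, "/"))
    rownames(Ztr) <- rownames(Zte) <- paste0("g", ci)
    if (learner == "lsq") {
      Y <- matrix(0, sum(tr), K)
      Y[cbind(seq_len(sum(tr)), as.integer(y[tr]))] <- 1
      Xa <- cbind(1, t(Ztr))
      B <- solve(crossprod(Xa) + diag(1e-8, ncol(Xa)), crossprod(Xa, Y))
      scores[!tr, ] <- cbind(1, t(Zte)) %*% B
    } else {
      fit <- fit_learner(Ztr, y[tr], learner = learner,
                         reg_strength = reg_strength)
      scores[!tr, ] <- predict_probs(fit, Zte)
    }
  }
  scores
}
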