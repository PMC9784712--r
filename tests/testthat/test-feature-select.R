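# Reproducibility filter, six ranking methods, aggregation, panel search.

test_that("reproducibility filter keeps r >= threshold, boundary included", {
  samples <- paste0("S", 1:4)
  a <- make_expr(c(1, 2, 3, 4,    1, 2, 3, 4,   1, 2, 3, 4),
                 c("AFFINE", "ANTI", "FLAT_B"), samples)
  b <- make_expr(c(3, 5, 7, 9,    4, 3, 2, 1,   1, 2, 3, 4),
                 c("AFFINE", "ANTI", "FLAT_B"), samples)
  b[b$gene == "FLAT_B", -1] <- as.list(rep(2, 4))
  out <- correlation_reproducibility_filter(a, b)
  expect_equal(out$r[out$gene == "AFFINE"], 1)
  expect_true(out$retained[out$gene == "AFFINE"])
  expect_equal(out$r[out$gene == "ANTI"], -1)
  expect_false(out$retained[out$gene == "ANTI"])
  expect_false(out$retained[out$gene == "FLAT_B"])
  expect_match(out$reason[out$gene == "FLAT_B"], "zero variance")

  # a gene at exactly the threshold is retained ("lower than" eliminates):
  # set the threshold to the gene's own r and check it survives
  av <- c(1, 2, 3, 4, 5)
  bv <- c(2, 1, 4, 3, 6)
  a1 <- make_expr(av, "G", paste0("S", 1:5))
  b1 <- make_expr(bv, "G", paste0("S", 1:5))
  r_exact <- correlation_reproducibility_filter(a1, b1, threshold = -1)$r
  res <- correlation_reproducibility_filter(a1, b1, threshold = r_exact)
  expect_true(res$retained)
  res_above <- correlation_reproducibility_filter(a1, b1,
                                                  threshold = r_exact + 1e-9)
  expect_false(res_above$retained)

  expect_error(correlation_reproducibility_filter(a[, 1:3], b[, 1:3]), "3 shared")
})

test_that("raising the reproducibility threshold never adds genes", {
  coh <- generate_cohort(n_cl = 20, n_mes = 20, n_pn = 20, seed = 2)
  b <- emulate_second_platform(coh$expression, noise_sd = 1.2, seed = 3)
  kept <- lapply(c(0.3, 0.5, 0.65, 0.8, 0.95), function(th) {
    out <- correlation_reproducibility_filter(coh$expression, b, threshold = th)
    out$gene[out$retained]
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("ANOVA scoring caps perfect separation and zeroes null genes", {
  samples <- paste0("S", 1:6)
  labels <- label_tbl(samples, rep(c("CL", "MES", "PN"), each = 2))
  x <- make_expr(c(0, 0, 5, 5, 10, 10,    # perfectly separated
                   1, 2, 1, 2, 1, 2,      # identical group means -> F = 0
                   0, 1, 4, 6, 9, 11),    # ordinary signal
                 c("PERFECT", "NULL", "SIG"), samples)
  rk <- score_features(x, labels, methods = "anova")
  f_sig <- rk$score[rk$gene == "SIG"]
  expect_equal(rk$score[rk$gene == "NULL"], 0)
  expect_true(is.finite(rk$score[rk$gene == "PERFECT"]))
  expect_equal(rk$score[rk$gene == "PERFECT"], 10 * f_sig)
  # mean-normalised scores average to 1
  expect_equal(mean(rk$score_norm), 1)

  # one-sample class errors
  bad <- label_tbl(samples, c("CL", "CL", "MES", "MES", "PN", "CL"))
  expect_error(score_features(x, bad, methods = "anova"), "PN")
  expect_error(score_features(x, labels, methods = "nonsense"), "unknown")
})

test_that("gain ratio of a binarised perfectly-predictive gene is 1", {
  samples <- paste0("S", 1:8)
  labels <- label_tbl(samples, rep(c("CL", "MES"), each = 4))
  x <- make_expr(c(1, 1, 1, 1, 9, 9, 9, 9), "G", samples)
  rk <- score_features(x, labels, methods = "gain_ratio", bins = 2)
  expect_equal(rk$score, 1)
})

test_that("discrete rankers match the brute-force entropy oracle", {
  # exhaustive-ish sweep of tiny discrete instances: <= 4 genes, <= 8 samples
  set.seed(99)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    p <- sample(2:4, 1)
    disc <- matrix(sample(1:2, n * p, replace = TRUE), p, n,
                   dimnames = list(paste0("G", 1:p), paste0("S", 1:n)))
    y <- factor(sample(c("CL", "MES"), n, replace = TRUE))
    if (length(unique(y)) < 2) next
    # feed the discrete values directly; 2-bin equal-frequency discretisation
    # of a two-valued vector is the identity partition
    x <- tibble::as_tibble(cbind(tibble::tibble(gene = rownames(disc)),
                                 tibble::as_tibble(as.data.frame(disc))))
    labels <- label_tbl(colnames(disc), as.character(y))
    rk <- score_features(x, labels, methods = c("gini", "gain_ratio", "fcbf", "mrmr"),
                         bins = 2)
    for (g in rownames(disc)) {
      xd <- disc[g, ]
      if (length(unique(xd)) == 1) xd <- rep(1L, n)
      expect_equal(rk$score[rk$method == "gini" & rk$gene == g],
                   oracle_gini_decrease(xd, y), tolerance = 1e-12)
      expect_equal(rk$score[rk$method == "gain_ratio" & rk$gene == g],
                   oracle_gain_ratio(xd, y), tolerance = 1e-12)
      expect_equal(rk$score[rk$method == "fcbf" & rk$gene == g],
                   oracle_su(xd, y), tolerance = 1e-12)
    }
    # mRMR selection order: scores p - rank must match the brute-force greedy
    ord <- oracle_mrmr_order(disc, y)
    mr <- rk[rk$method == "mrmr", ]
    expect_equal(mr$score[match(rownames(disc)[ord], mr$gene)],
                 p - seq_len(p))
  }
})

test_that("rankings are invariant to sample order and die under label shuffling", {
  coh <- generate_cohort(n_cl = 25, n_mes = 25, n_pn = 25, delta = 3, sigma = 1,
                         n_noise_genes = 20, seed = 31)
  x <- coh$expression
  labels <- coh$labels
  methods <- c("anova", "relieff", "gini", "gain_ratio", "fcbf", "mrmr")
  rk1 <- score_features(x, labels, methods = methods)

  # permute sample columns (labels travel with their samples)
  perm <- withr::with_seed(5, sample(2:ncol(x)))
  xp <- x[, c(1, perm)]
  rk2 <- score_features(xp, labels, methods = methods)
  expect_equal(dplyr::arrange(rk1, method, gene), dplyr::arrange(rk2, method, gene),
               tolerance = 1e-10, ignore_attr = TRUE)

  # planted genes outrank noise genes with true labels...
  planted <- default_pattern()$gene
  agg <- aggregate_rankings(rk1, k = 20)
  planted_rank <- mean(agg$rank[agg$gene %in% planted])
  noise_rank <- mean(agg$rank[!agg$gene %in% planted])
  expect_lt(planted_rank, noise_rank - 5)

  # ...but not after uniform label shuffling (mean ranks roughly equal)
  diffs <- sapply(1:5, function(i) {
    sh <- labels
    sh$subtype <- withr::with_seed(100 + i, sample(sh$subtype))
    rks <- score_features(x, sh, methods = c("anova", "gini"))
    aggs <- aggregate_rankings(rks, k = 20)
    mean(aggs$rank[aggs$gene %in% planted]) - mean(aggs$rank[!aggs$gene %in% planted])
  })
  expect_lt(abs(mean(diffs)), 5)
})

test_that("aggregation is scale-invariant and reduces to a single method", {
  coh <- generate_cohort(n_cl = 15, n_mes = 15, n_pn = 15, seed = 8)
  rk <- score_features(coh$expression, coh$labels, methods = "anova")
  agg1 <- aggregate_rankings(rk, k = 5)
  expect_equal(panel_genes(agg1),
               rk$gene[order(-rk$score, rk$gene)][1:5])

  # a second method with proportional raw scores leaves the order unchanged
  rk2 <- rk
  rk2$method <- "gini"
  rk2$score <- rk$score * 7
  rk2$score_norm <- rk2$score / mean(rk2$score)
  agg2 <- aggregate_rankings(dplyr::bind_rows(rk, rk2), k = 5)
  expect_equal(panel_genes(agg2), panel_genes(agg1))
  expect_equal(agg2$cumulative, 2 * agg1$cumulative[match(agg2$gene, agg1$gene)],
               tolerance = 1e-12)

  expect_error(aggregate_rankings(rk[0, ], k = 2), "empty")
  expect_error(aggregate_rankings(rk, k = 100), "exceeds")
})

test_that("planted discriminative genes take the top cumulative ranks", {
  hits <- sapply(1:10, function(s) {
    coh <- generate_cohort(n_cl = 30, n_mes = 30, n_pn = 30, delta = 3, sigma = 1,
                           n_noise_genes = 20, seed = 200 + s)
    # keep three strongly planted genes plus the noise block
    keep <- c("KLRC3", "MET", "EGFR", sprintf("NOISE%02d", 1:20))
    x <- coh$expression[coh$expression$gene %in% keep, ]
    rk <- score_features(x, coh$labels)
    agg <- aggregate_rankings(rk, k = 3)
    all(c("KLRC3", "MET", "EGFR") %in% panel_genes(agg))
  })
  expect_gte(sum(hits), 9)
})

test_that("panel search returns forced choices, respects caps, finds signal", {
  # five non-redundant planted contrasts among pure-noise genes: exact
  # recovery is identifiable (two genes sharing a block would be
  # exchangeable with noise at saturated accuracy)
  pat <- tibble::tibble(gene = paste0("SIG", 1:5),
                        CL  = c(1, 0, 0, -1, 0),
                        MES = c(0, 1, 0, 0, -1),
                        PN  = c(0, 0, 1, 0, 0))
  coh <- generate_cohort(n_cl = 50, n_mes = 50, n_pn = 50, pattern = pat,
                         delta = 3, sigma = 1, n_noise_genes = 5, seed = 77)
  five <- pat$gene
  # forced choice: candidates of exactly panel_size
  sr1 <- search_best_panel(coh$expression, coh$labels, five, panel_size = 5,
                           cv_folds = 5, seed = 1)
  expect_equal(nrow(sr1), 1)
  expect_setequal(panel_genes(sr1), five)

  # combination count: C(10, 5) = 252 rows
  cand10 <- c(five, sprintf("NOISE%02d", 1:5))
  sr2 <- search_best_panel(coh$expression, coh$labels, cand10, panel_size = 5,
                           cv_folds = 5, seed = 1)
  expect_equal(nrow(sr2), choose(10, 5))
  # only the five planted genes carry signal
  expect_setequal(panel_genes(sr2), five)

  # cap guards the search space
  expect_error(search_best_panel(coh$expression, coh$labels, cand10,
                                 panel_size = 5, max_combinations = 100),
               "heuristic")
})

test_that("lsq search accuracies agree with an independent per-panel CV", {
  coh <- generate_cohort(n_cl = 20, n_mes = 20, n_pn = 20, delta = 2, sigma = 1,
                         n_noise_genes = 2, seed = 13)
  cand <- c("KLRC3", "EGFR", "MET", "NOISE01", "NOISE02")
  sr <- search_best_panel(coh$expression, coh$labels, cand, panel_size = 2,
                          cv_folds = 5, seed = 21)
  # re-evaluate each combination with the package's own lsq cross-validation
  for (i in seq_len(nrow(sr))) {
    genes <- strsplit(sr$panel[i], ",")[[1]]
    cv <- cross_validate(coh$expression, coh$labels, genes, learner = "lsq",
                         folds = 5, seed = 21)
    expect_equal(sr$accuracy[i], cv$accuracy, tolerance = 1e-12)
  }
})
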