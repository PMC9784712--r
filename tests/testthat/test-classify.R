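# Classifier training, cross-validation, prediction, persistence.

test_that("training produces the contracted shapes and separable accuracy", {
  coh <- generate_cohort(n_cl = 20, n_mes = 20, n_pn = 20, delta = 4,
                         sigma = 0.2, seed = 4)
  model <- train_classifier(coh$expression, coh$labels, five_gene_panel())
  expect_s3_class(model, "subtype_model")
  expect_equal(dim(model$coefficients), c(3, 5))
  expect_equal(model$classes, c("CL", "MES", "PN"))
  expect_equal(rownames(model$coefficients), c("CL", "MES", "PN"))

  pred <- predict_cohort(model, coh$expression)
  expect_equal(pred$subtype, coh$labels$subtype)  # near-noiseless: perfect

  # tidy()/glance() expose the fit
  td <- tidy(model)
  expect_equal(nrow(td), 3 * 6)  # 3 classes x (intercept + 5 genes)
  expect_equal(glance(model)$n_genes, 5)
})

test_that("training validates panel genes and class presence", {
  coh <- generate_cohort(n_cl = 10, n_mes = 10, n_pn = 10, seed = 4)
  expect_error(train_classifier(coh$expression, coh$labels,
                                c("EGFR", "NOT_A_GENE")), "NOT_A_GENE")
  two_class <- coh$labels[coh$labels$subtype != "PN", ]
  x2 <- coh$expression[, c("gene", two_class$sample)]
  expect_error(train_classifier(x2, two_class, five_gene_panel()), "PN")
})

test_that("a strong L1 penalty zeroes coefficients", {
  coh <- generate_cohort(n_cl = 30, n_mes = 30, n_pn = 30, delta = 1,
                         sigma = 1, seed = 6)
  weak <- train_classifier(coh$expression, coh$labels, five_gene_panel(),
                           reg_strength = 10)
  strong <- train_classifier(coh$expression, coh$labels, five_gene_panel(),
                             reg_strength = 0.005)
  expect_gt(sum(strong$coefficients == 0), sum(weak$coefficients == 0))
  expect_gt(sum(strong$coefficients == 0), 0)
})

test_that("stratified folds keep class counts within one of proportional", {
  # development-cohort class sizes: MES 151, CL 140, PN 128
  coh <- generate_cohort(n_cl = 140, n_mes = 151, n_pn = 128, seed = 10)
  y <- factor(coh$labels$subtype)
  fold <- gliotype:::stratified_folds(y, 10, seed = 1)
  tab <- table(fold, y)
  for (cl in colnames(tab)) {
    target <- sum(y == cl) / 10
    expect_true(all(abs(tab[, cl] - target) <= 1))
  }
})

test_that("cross-validation is deterministic, leak-free and separably perfect", {
  coh <- generate_cohort(n_cl = 20, n_mes = 20, n_pn = 20, delta = 4,
                         sigma = 0.2, seed = 12)
  cv1 <- cross_validate(coh$expression, coh$labels, five_gene_panel(),
                        folds = 5, seed = 3)
  cv2 <- cross_validate(coh$expression, coh$labels, five_gene_panel(),
                        folds = 5, seed = 3)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(cv1$accuracy, 1)

  # every class must support the fold count
  small <- generate_cohort(n_cl = 4, n_mes = 10, n_pn = 10, seed = 12)
  expect_error(cross_validate(small$expression, small$labels,
                              five_gene_panel(), folds = 5), "folds")
})

test_that("label permutation drives CV accuracy to chance", {
  coh <- generate_cohort(n_cl = 30, n_mes = 30, n_pn = 30, delta = 2,
                         sigma = 1, seed = 15)
  accs <- sapply(1:20, function(i) {
    sh <- coh$labels
    sh$subtype <- withr::with_seed(1000 + i, sample(sh$subtype))
    cross_validate(coh$expression, sh, five_gene_panel(), learner = "lsq",
                   folds = 5, seed = i)$accuracy
  })
  # 20 shuffles x 90 samples: chance is 1/3, Monte-Carlo sd of the mean ~ 0.011
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})

test_that("probabilities are simplex-valued and arg-max assigns the subtype", {
  coh <- generate_cohort(n_cl = 15, n_mes = 15, n_pn = 15, seed = 19)
  model <- train_classifier(coh$expression, coh$labels, five_gene_panel())
  new <- generate_cohort(n_cl = 10, n_mes = 10, n_pn = 10, seed = 20)
  pred <- predict_cohort(model, new$expression)
  pm <- as.matrix(pred[c("p_CL", "p_MES", "p_PN")])
  expect_true(all(pm >= 0))
  expect_lt(max(abs(rowSums(pm) - 1)), 1e-9)
  expect_equal(pred$subtype,
               c("CL", "MES", "PN")[max.col(pm, ties.method = "first")])
})

test_that("cohort-mode prediction is invariant to per-gene additive shifts", {
  coh <- generate_cohort(n_cl = 15, n_mes = 15, n_pn = 15, seed = 23)
  model <- train_classifier(coh$expression, coh$labels, five_gene_panel())
  new <- generate_cohort(n_cl = 10, n_mes = 10, n_pn = 10, seed = 24)
  shifted <- new$expression
  idx <- which(shifted$gene == "EGFR")
  shifted[idx, -1] <- shifted[idx, -1] + 100
  p0 <- predict_cohort(model, new$expression, norm_mode = "cohort")
  p1 <- predict_cohort(model, shifted, norm_mode = "cohort")
  expect_equal(p0$p_PN, p1$p_PN, tolerance = 1e-9)
  expect_equal(p0$subtype, p1$subtype)
})

test_that("prediction-time contracts: missing genes, single samples, constants", {
  coh <- generate_cohort(n_cl = 10, n_mes = 10, n_pn = 10, seed = 27)
  model <- train_classifier(coh$expression, coh$labels, five_gene_panel())
  new <- generate_cohort(n_cl = 5, n_mes = 5, n_pn = 5, seed = 28)
  dropped <- new$expression[new$expression$gene != "KLRC3", ]
  expect_error(predict_cohort(model, dropped), "KLRC3")
  one <- new$expression[, 1:2]
  expect_error(predict_cohort(model, one, norm_mode = "cohort"), "stored")
  # stored mode handles the single sample
  p1 <- predict_cohort(model, one, norm_mode = "stored")
  expect_equal(nrow(p1), 1)
  # constant gene in cohort mode errors
  flat <- new$expression
  flat[flat$gene == "VAV3", -1] <- as.list(rep(1, ncol(flat) - 1))
  expect_error(predict_cohort(model, flat, norm_mode = "cohort"), "VAV3")
})

test_that("a cohort drawn from the PN block pattern is called PN throughout", {
  for (s in 1:5) {
    train <- generate_cohort(n_cl = 20, n_mes = 20, n_pn = 20, delta = 3,
                             sigma = 1, seed = 300 + s)
    model <- train_classifier(train$expression, train$labels, five_gene_panel())
    # same assay scale as training (shared baselines), fresh noise
    pn_only <- generate_cohort(n_cl = 0, n_mes = 0, n_pn = 20, delta = 3,
                               sigma = 1, seed = 400 + s,
                               baseline_seed = 300 + s)
    pred <- predict_cohort(model, pn_only$expression, norm_mode = "stored")
    expect_true(all(pred$subtype == "PN"))
  }
})

test_that("model persistence round-trips predictions bit-identically", {
  coh <- generate_cohort(n_cl = 15, n_mes = 15, n_pn = 15, seed = 33)
  new <- generate_cohort(n_cl = 8, n_mes = 8, n_pn = 8, seed = 34)
  for (lrn in c("logreg_l1", "linear_svm")) {
    model <- train_classifier(coh$expression, coh$labels, five_gene_panel(),
                              learner = lrn)
    tf <- withr::local_tempfile(fileext = ".json")
    write_model(model, tf)
    back <- read_model(tf)
    expect_identical(predict_cohort(model, new$expression),
                     predict_cohort(back, new$expression))
  }
})

test_that("20-gene and 5-gene models mostly agree at moderate noise", {
  coh <- generate_cohort(n_cl = 60, n_mes = 60, n_pn = 60, delta = 2,
                         sigma = 1, seed = 41)
  m20 <- train_classifier(coh$expression, coh$labels, default_pattern()$gene)
  m5 <- train_classifier(coh$expression, coh$labels, five_gene_panel())
  new <- generate_cohort(n_cl = 20, n_mes = 20, n_pn = 20, delta = 2,
                         sigma = 1, seed = 42)
  p20 <- predict_cohort(m20, new$expression)
  p5 <- predict_cohort(m5, new$expression)
  agreement <- mean(p20$subtype == p5$subtype)
  # tracked as a regression guard: the two panels should agree on most samples
  expect_gt(agreement, 0.5)
})

test_that("the linear SVM learner trains, predicts and cross-validates", {
  coh <- generate_cohort(n_cl = 25, n_mes = 25, n_pn = 25, delta = 2.5,
                         sigma = 1, seed = 51)
  cv <- cross_validate(coh$expression, coh$labels, five_gene_panel(),
                       learner = "linear_svm", folds = 5, seed = 2)
  expect_gt(cv$accuracy, 0.8)
  pm <- as.matrix(cv$predictions[c("p_CL", "p_MES", "p_PN")])
  expect_lt(max(abs(rowSums(pm) - 1)), 1e-9)
})
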