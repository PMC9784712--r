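# Three-class subtype classifiers: multinomial L1 logistic regression
# (primary) and one-vs-rest linear SVM with Platt probability calibration
# (alternative). Both reduce to a linear score per class so fitted models
# serialise to plain coefficient matrices.

# Fit a learner on a standardised genes x samples matrix Z. Returns the
# linear parametrisation only.
fit_learner <- function(Z, y, learner = c("logreg_l1", "linear_svm"),
                        reg_strength = 1, seed = 1) {
  learner <- match.arg(learner)
  X <- t(Z)
  classes <- subtype_levels()
  p <- nrow(Z)
  if (learner == "logreg_l1") {
    # glmnet minimises (1/n) * deviance + lambda * |beta|_1; reg_strength C
    # maps to lambda = 1 / (n * C), so larger C means weaker penalty.
    lambda_t <- 1 / (nrow(X) * reg_strength)
    path <- lambda_t * c(100, 50, 20, 10, 5, 2, 1)
    fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 1,
                          lambda = path, standardize = FALSE, maxit = 1e6)
    co <- coef(fit, s = lambda_t)
    coefs <- t(vapply(classes, function(cl) as.numeric(co[[cl]])[-1], numeric(p)))
    intercepts <- vapply(classes, function(cl) as.numeric(co[[cl]])[1], numeric(1))
    platt <- NULL
  } else {
    coefs <- matrix(0, 3, p)
    intercepts <- numeric(3)
    platt <- matrix(0, 3, 2, dimnames = list(classes, c("a", "b")))
    for (i in seq_along(classes)) {
      cl <- classes[i]
      yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
      svmfit <- withr::with_seed(seed, e1071::svm(
        x = X, y = yy, kernel = "linear", cost = reg_strength, scale = FALSE))
      w <- as.numeric(t(svmfit$coefs) %*% svmfit$SV)
      b <- -svmfit$rho
      # e1071 orients decision values positive towards the first factor level
      # ("pos"); verify and flip if the installed build differs.
      d_train <- as.numeric(X %*% w + b)
      if (mean(d_train[yy == "pos"]) < mean(d_train[yy == "rest"])) {
        w <- -w
        b <- -b
        d_train <- -d_train
      }
      coefs[i, ] <- w
      intercepts[i] <- b
      pl <- suppressWarnings(glm((yy == "pos") ~ d_train, family = binomial()))
      platt[i, ] <- c(unname(coef(pl)[2]), unname(coef(pl)[1]))
    }
  }
  dimnames(coefs) <- list(classes, rownames(Z))
  names(intercepts) <- classes
  list(learner = learner, reg_strength = reg_strength, seed = seed,
       classes = classes, coefficients = coefs, intercepts = intercepts,
       platt = platt)
}

# Per-sample class probabilities from a fitted linear parametrisation.
predict_probs <- function(fit, Z) {
  eta <- t(fit$coefficients %*% Z + fit$intercepts)  # samples x classes
  if (fit$learner == "logreg_l1" || is.null(fit$platt)) {
    eta <- eta - apply(eta, 1, max)
    q <- exp(eta)
  } else {
    q <- vapply(seq_len(3), function(i) {
      stats::plogis(fit$platt[i, "b"] + fit$platt[i, "a"] * eta[, i])
    }, numeric(nrow(eta)))
    q <- matrix(q, ncol = 3)
    q[q < 1e-12] <- 1e-12
  }
  probs <- q / rowSums(q)
  colnames(probs) <- fit$classes
  probs
}

#' Train a three-class subtype classifier
#'
#' Restricts the cohort to the panel genes, standardises each gene
#' (population z-score across the training cohort, the parameters are kept in
#' the model for later stored-mode prediction), and fits either a multinomial
#' L1-penalised (LASSO) logistic regression or a one-vs-rest linear SVM with
#' Platt-calibrated probabilities.
#'
#' @param x Wide expression tibble (or genes x samples matrix) on the
#'   log-expression scale.
#' @param labels Subtype labels; all three of CL, MES, PN must be present.
#' @param panel Gene panel (character vector or object with a panel
#'   attribute).
#' @param learner `"logreg_l1"` (default) or `"linear_svm"`.
#' @param reg_strength Regularisation strength C > 0 (default 1); larger is
#'   weaker regularisation. For the logistic model C maps to the glmnet
#'   penalty lambda = 1/(nC).
#' @param seed Seed recorded in the model (the logistic fit itself is
#'   deterministic).
#' @param dataset_tag Free-text provenance tag stored in the model.
#' @return A `subtype_model`: panel, class order (CL, MES, PN), coefficient
#'   matrix (classes x genes), intercepts, learner spec, and the training
#'   standardisation parameters. Supports [predict_cohort()],
#'   [generics::tidy()] and [generics::glance()].
#' @export
train_classifier <- function(x, labels, panel,
                             learner = c("logreg_l1", "linear_svm"),
                             reg_strength = 1, seed = 1, dataset_tag = NULL) {
  learner <- match.arg(learner)
  if (reg_strength <= 0) abort("reg_strength must be > 0")
  m <- expr_mat(x)
  panel <- panel_genes(panel)
  absent <- setdiff(panel, rownames(m))
  if (length(absent)) {
    abort(paste0("panel gene(s) absent from matrix: ", paste(absent, collapse = ", ")))
  }
  y <- align_labels(labels, colnames(m))
  missing_cls <- setdiff(subtype_levels(), unique(as.character(y)))
  if (length(missing_cls)) {
    abort(paste0("class(es) absent from training labels: ",
                 paste(missing_cls, collapse = ", ")))
  }
  zs <- zscore_genes(m[panel, , drop = FALSE])
  params <- norm_params(zs)[c("gene", "mu", "sigma")]
  Z <- expr_mat(zs)
  fit <- fit_learner(Z, y, learner = learner, reg_strength = reg_strength,
                     seed = seed)
  structure(c(fit, list(
    panel = panel,
    norm_params = params,
    provenance = list(dataset_tag = dataset_tag %||% "unspecified",
                      trained_at = as.character(Sys.Date()),
                      n_samples = ncol(m))
  )), class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("<subtype_model> ", x$learner, ", C = ", x$reg_strength, "\n",
      "  panel (", length(x$panel), "): ", paste(x$panel, collapse = ", "), "\n",
      "  classes: ", paste(x$classes, collapse = ", "),
      " | trained on ", x$provenance$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Stratified cross-validation of a subtype classifier
#'
#' Assigns samples to stratified folds (per-class counts within one of exact
#' proportionality), re-estimates the per-gene standardisation inside each
#' training fold and applies it to the held-out fold (no leakage), then pools
#' the out-of-fold predictions into overall accuracy, per-class accuracy and
#' per-class one-vs-rest AUC.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds (default 10); every class must have at least
#'   `folds` samples.
#' @return A `subtype_cv` object: `accuracy`, `per_class` (tibble), `auc`
#'   (tibble), `mean_auc`, and the pooled `predictions` tibble (`sample`,
#'   `fold`, `reference`, `predicted`, `p_CL`, `p_MES`, `p_PN`). Deterministic
#'   given the seed.
#' @export
cross_validate <- function(x, labels, panel, learner = "logreg_l1",
                           folds = 10, reg_strength = 1, seed = 1) {
  learner <- match.arg(learner, c("logreg_l1", "linear_svm", "lsq"))
  m <- expr_mat(x)
  panel <- panel_genes(panel)
  absent <- setdiff(panel, rownames(m))
  if (length(absent)) {
    abort(paste0("panel gene(s) absent from matrix: ", paste(absent, collapse = ", ")))
  }
  y <- align_labels(labels, colnames(m))
  fold <- stratified_folds(y, folds, seed)
  M <- m[panel, , drop = FALSE]
  n <- ncol(M)
  probs <- matrix(NA_real_, n, 3, dimnames = list(colnames(M), subtype_levels()))
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- rowMeans(M[, tr, drop = FALSE])
    sg <- row_sd_pop(M[, tr, drop = FALSE])
    sg[sg == 0] <- 1  # constant gene in a fold carries no information
    Ztr <- (M[, tr, drop = FALSE] - mu) / sg
    Zte <- (M[, !tr, drop = FALSE] - mu) / sg
    if (learner == "lsq") {
      K <- 3
      Y <- matrix(0, sum(tr), K)
      Y[cbind(seq_len(sum(tr)), as.integer(y[tr]))] <- 1
      Xa <- cbind(1, t(Ztr))
      B <- solve(crossprod(Xa) + diag(1e-8, ncol(Xa)), crossprod(Xa, Y))
      sc <- cbind(1, t(Zte)) %*% B
      sc <- exp(sc - apply(sc, 1, max))
      probs[!tr, ] <- sc / rowSums(sc)
    } else {
      fit <- fit_learner(Ztr, y[tr], learner = learner,
                         reg_strength = reg_strength, seed = seed)
      probs[!tr, ] <- predict_probs(fit, Zte)
    }
  }
  predicted <- factor(subtype_levels()[max.col(probs, ties.method = "first")],
                      levels = subtype_levels())
  acc <- mean(predicted == y)
  per_class <- tibble::tibble(
    subtype = subtype_levels(),
    n = as.integer(table(y)[subtype_levels()]),
    accuracy = vapply(subtype_levels(), function(cl) {
      idx <- y == cl
      if (!any(idx)) NA_real_ else mean(predicted[idx] == cl)
    }, numeric(1))
  )
  auc <- tibble::tibble(
    subtype = subtype_levels(),
    auc = vapply(seq_len(3), function(i) {
      auc_trapezoid(probs[, i], y == subtype_levels()[i])
    }, numeric(1))
  )
  structure(list(
    accuracy = acc, per_class = per_class, auc = auc,
    mean_auc = mean(auc$auc, na.rm = TRUE),
    predictions = tibble::tibble(
      sample = colnames(M), fold = fold,
      reference = as.character(y), predicted = as.character(predicted),
      p_CL = probs[, "CL"], p_MES = probs[, "MES"], p_PN = probs[, "PN"]
    ),
    learner = learner, folds = folds, seed = seed, panel = panel
  ), class = "subtype_cv")
}

#' @export
print.subtype_cv <- function(x, ...) {
  cat("<subtype_cv> ", x$folds, "-fold, ", x$learner,
      " | accuracy ", sprintf("%.3f", x$accuracy),
      ", mean OvR AUC ", sprintf("%.3f", x$mean_auc), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' Classify a cohort with a fitted subtype model
#'
#' Standardises the cohort per `norm_mode` and applies the model's linear
#' scores: `"cohort"` (default) re-estimates each gene's mean and standard
#' deviation from the new cohort itself — the mode used when an entire new
#' cohort is profiled together — while `"stored"` applies the training-time
#' parameters kept in the model, the only option for single samples.
#'
#' @param model A `subtype_model` from [train_classifier()] or [read_model()].
#' @param x Wide expression tibble (or genes x samples matrix) containing all
#'   panel genes.
#' @param norm_mode `"cohort"` or `"stored"`.
#' @return Prediction tibble: `sample`, `subtype` (arg-max class), `p_CL`,
#'   `p_MES`, `p_PN` (each row sums to 1); `norm_mode` kept as an attribute.
#' @export
predict_cohort <- function(model, x, norm_mode = c("cohort", "stored")) {
  norm_mode <- match.arg(norm_mode)
  if (!inherits(model, "subtype_model")) abort("`model` must be a subtype_model")
  m <- expr_mat(x)
  absent <- setdiff(model$panel, rownames(m))
  if (length(absent)) {
    abort(paste0("panel gene(s) absent from input: ", paste(absent, collapse = ", ")))
  }
  M <- m[model$panel, , drop = FALSE]
  if (norm_mode == "cohort") {
    if (ncol(M) < 2) {
      abort("cohort-mode prediction needs >= 2 samples; use norm_mode = \"stored\"")
    }
    Z <- expr_mat(zscore_genes(M))
  } else {
    Z <- expr_mat(zscore_genes(M, params = model$norm_params))
  }
  probs <- predict_probs(model, Z)
  out <- tibble::tibble(
    sample = colnames(M),
    subtype = model$classes[max.col(probs, ties.method = "first")],
    p_CL = probs[, "CL"], p_MES = probs[, "MES"], p_PN = probs[, "PN"]
  )
  attr(out, "norm_mode") <- norm_mode
  out
}
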