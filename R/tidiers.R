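# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted subtype model into a long coefficient table
#'
#' @param x A `subtype_model`.
#' @param ... Unused.
#' @return Tibble with one row per class x term (intercept + panel genes):
#'   `subtype`, `term`, `estimate`.
#' @export
tidy.subtype_model <- function(x, ...) {
  co <- cbind(`(Intercept)` = x$intercepts, x$coefficients)
  tibble::tibble(
    subtype = rep(x$classes, each = ncol(co)),
    term = rep(colnames(co), times = nrow(co)),
    estimate = as.numeric(t(co))
  )
}

#' One-row summary of a fitted subtype model
#'
#' @param x A `subtype_model`.
#' @param ... Unused.
#' @return Tibble: `learner`, `reg_strength`, `n_genes`, `n_samples`,
#'   `n_zero_coef` (exact zeros induced by the L1 penalty), `seed`.
#' @export
glance.subtype_model <- function(x, ...) {
  tibble::tibble(
    learner = x$learner,
    reg_strength = x$reg_strength,
    n_genes = length(x$panel),
    n_samples = x$provenance$n_samples %||% NA_integer_,
    n_zero_coef = sum(x$coefficients == 0),
    seed = x$seed
  )
}

#' Tidy cross-validation results into per-class metrics
#'
#' @param x A `subtype_cv` from [cross_validate()].
#' @param ... Unused.
#' @return Tibble: `subtype`, `n`, `accuracy`, `auc`.
#' @export
tidy.subtype_cv <- function(x, ...) {
  dplyr::left_join(x$per_class, x$auc, by = "subtype")
}

#' One-row summary of a cross-validation run
#'
#' @param x A `subtype_cv`.
#' @param ... Unused.
#' @return Tibble: `accuracy`, `mean_auc`, `folds`, `learner`, `seed`.
#' @export
glance.subtype_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, mean_auc = x$mean_auc,
                 folds = x$folds, learner = x$learner, seed = x$seed)
}

#' Tidy an evaluation report into per-class accuracies
#'
#' @param x A `subtype_eval` from [confusion_and_accuracy()].
#' @param ... Unused.
#' @return The per-class tibble (`subtype`, `n`, `accuracy`).
#' @export
tidy.subtype_eval <- function(x, ...) x$per_class

#' @rdname tidy.subtype_eval
#' @export
glance.subtype_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$confusion))
}

#' Tidy one-vs-rest ROC results into per-class AUCs
#'
#' @param x A `subtype_roc` from [roc_one_vs_rest()].
#' @param ... Unused.
#' @return The AUC tibble (`subtype`, `auc`).
#' @export
tidy.subtype_roc <- function(x, ...) x$auc
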