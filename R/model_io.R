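# Versioned JSON persistence of fitted subtype models.

MODEL_FORMAT_VERSION <- "1.0"

#' Save a fitted subtype model as JSON
#'
#' Writes the full linear parametrisation (panel, class order, coefficient
#' matrix, intercepts, Platt calibration if present), the learner spec, the
#' training standardisation parameters and the provenance block, at full
#' numeric precision so that save/load/predict reproduces probabilities
#' bit-identically.
#'
#' @param model A `subtype_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "subtype_model")) abort("`model` must be a subtype_model")
  payload <- list(
    format = "gliotype-model",
    format_version = MODEL_FORMAT_VERSION,
    learner = model$learner,
    reg_strength = model$reg_strength,
    seed = model$seed,
    classes = model$classes,
    panel = model$panel,
    coefficients = unname(apply(model$coefficients, 1, as.numeric,
                                simplify = FALSE)),
    intercepts = as.numeric(model$intercepts),
    platt = if (is.null(model$platt)) NULL else
      unname(apply(model$platt, 1, as.numeric, simplify = FALSE)),
    norm_params = list(gene = model$norm_params$gene,
                       mu = model$norm_params$mu,
                       sigma = model$norm_params$sigma),
    provenance = model$provenance
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly,
  # so save -> load -> predict is bit-identical.
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a subtype model saved by [write_model()]
#' @param path Path to the model JSON file.
#' @return A `subtype_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "gliotype-model")) {
    abort("not a gliotype model file")
  }
  classes <- as.character(j$classes)
  panel <- as.character(j$panel)
  as_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }
  co <- as_mat(j$coefficients)
  dimnames(co) <- list(classes, panel)
  platt <- NULL
  if (!is.null(j$platt) && length(j$platt)) {
    platt <- as_mat(j$platt)
    dimnames(platt) <- list(classes, c("a", "b"))
  }
  structure(list(
    learner = j$learner, reg_strength = j$reg_strength, seed = j$seed,
    classes = classes, coefficients = co,
    intercepts = setNames(as.numeric(j$intercepts), classes),
    platt = platt, panel = panel,
    norm_params = tibble::tibble(gene = as.character(j$norm_params$gene),
                                 mu = as.numeric(j$norm_params$mu),
                                 sigma = as.numeric(j$norm_params$sigma)),
    provenance = j$provenance
  ), class = "subtype_model")
}
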