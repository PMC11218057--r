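#' Specify the regression model for design generation and fitting
#'
#' An interaction model over coded factor levels: intercept, main effects and
#' two-factor interaction products, plus optional higher-order products such
#' as a three-factor term. The same specification drives the D-optimality
#' criterion, the model matrix and the fitted coefficient layout, so the
#' design is optimal for exactly the model that is later fitted.
#'
#' @param factors a [factor_set()] or character vector of factor names.
#' @param interactions `TRUE` for all two-factor interactions (the default
#'   "interaction design"), `FALSE` for main effects only, or a list of
#'   character pairs to include a subset.
#' @param extra optional list of character vectors naming higher-order
#'   product terms, e.g. `list(c("HS", "PEG", "PVA"))`.
#' @param intercept include an intercept column (default `TRUE`).
#' @return A `model_spec` object (list with `factors`, `main`,
#'   `interactions`, `extra`, `intercept`, and term labels `terms`).
#' @export
#' @examples
#' model_spec(c("A", "B", "C"))                 # 1 + 3 + 3 = 7 parameters
#' model_spec(c("A", "B"), interactions = FALSE)
model_spec <- function(factors, interactions = TRUE, extra = NULL,
                       intercept = TRUE) {
  fnames <- if (inherits(factors, "factor_set")) factors$name
            else as.character(factors)
  if (length(fnames) == 0) stop("empty factor list")
  if (isTRUE(interactions)) {
    ia <- if (length(fnames) >= 2) utils::combn(fnames, 2, simplify = FALSE)
          else list()
  } else if (isFALSE(interactions)) {
    ia <- list()
  } else {
    ia <- lapply(interactions, as.character)
  }
  extra <- lapply(extra %||% list(), as.character)
  all_terms <- c(ia, extra)
  for (tm in all_terms) {
    if (!all(tm %in% fnames))
      stop("term references undeclared factor: ", paste(tm, collapse = ":"))
    if (anyDuplicated(tm)) stop("repeated factor within a term")
  }
  labels <- c(if (intercept) "(Intercept)", fnames,
              vapply(all_terms, paste, "", collapse = ":"))
  if (anyDuplicated(labels)) stop("duplicate model terms")
  structure(list(factors = fnames, main = fnames, interactions = ia,
                 extra = extra, intercept = intercept, terms = labels),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of model parameters
#' @param model a [model_spec()].
#' @return Integer parameter count p.
#' @export
n_parameters <- function(model) length(model$terms)

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model: %d factors, %d interaction + %d extra terms, p = %d\n",
              length(x$main), length(x$interactions), length(x$extra),
              n_parameters(x)))
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Expand coded settings into the model matrix
#'
#' Builds the regression matrix for an interaction model from coded factor
#' levels: an intercept column, one column per main effect, and elementwise
#' products for interaction and higher-order terms. Column order follows
#' `model$terms` and is deterministic. A center-point row (all coded levels
#' zero) has zeros in every non-intercept column.
#'
#' @param design a `design_table` (see [d_optimal_design()]) or a numeric
#'   matrix of coded levels with one column per factor.
#' @param model a [model_spec()].
#' @return Numeric matrix with `nrow(design)` rows and `n_parameters(model)`
#'   columns, with term labels as column names.
#' @export
build_model_matrix <- function(design, model) {
  X <- if (inherits(design, "design_table")) coded_matrix(design)
       else .as_factor_matrix(design, data.frame(name = model$factors))
  if (nrow(X) == 0) stop("empty design")
  cols <- list()
  if (model$intercept) cols[["(Intercept)"]] <- rep(1, nrow(X))
  for (f in model$main) cols[[f]] <- X[, f]
  for (tm in c(model$interactions, model$extra)) {
    lab <- paste(tm, collapse = ":")
    cols[[lab]] <- apply(X[, tm, drop = FALSE], 1, prod)
  }
  mm <- do.call(cbind, cols)
  colnames(mm) <- names(cols)
  rownames(mm) <- rownames(X)
  mm
}
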