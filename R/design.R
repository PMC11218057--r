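#' Candidate set for D-optimal search
#'
#' Full factorial grid of coded levels, evenly spaced on \[-1, +1\], over all
#' factors. Three levels per factor (the default) keeps the mid level in the
#' candidate space so center points lie on the grid.
#'
#' @param factors a [factor_set()].
#' @param levels number of levels per factor (>= 2).
#' @return Numeric matrix of coded candidate points,
#'   `levels^nrow(factors)` rows.
#' @export
candidate_set <- function(factors, levels = 3) {
  if (!inherits(factors, "factor_set")) stop("'factors' must be a factor_set")
  if (nrow(factors) == 0) stop("empty factor list")
  if (levels < 2) stop("levels_per_factor must be >= 2")
  lev <- seq(-1, 1, length.out = levels)
  grid <- as.matrix(expand.grid(rep(list(lev), nrow(factors)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- factors$name
  grid
}

#' Assemble a design table from coded settings
#'
#' @param coded numeric matrix of coded levels (runs x factors).
#' @param factors a [factor_set()].
#' @param run_id optional run identifiers (default `R01`, `R02`, ...).
#' @param batch optional batch labels.
#' @return A `design_table`: data.frame with `run_id`, one column per factor
#'   in actual concentration units, `coded_<factor>` columns, `is_center`
#'   and `batch`; the factor set is kept as an attribute.
#' @export
design_table <- function(coded, factors, run_id = NULL, batch = NA_character_) {
  coded <- .as_factor_matrix(coded, factors)
  if (any(abs(coded) > 1 + 1e-9)) stop("coded levels must lie in [-1, +1]")
  n <- nrow(coded)
  run_id <- run_id %||% sprintf("R%02d", seq_len(n))
  if (anyDuplicated(run_id)) stop("run_ids must be unique")
  actual <- coded_to_actual(coded, factors)
  out <- data.frame(run_id = as.character(run_id), actual,
                    check.names = FALSE, stringsAsFactors = FALSE)
  cm <- as.data.frame(coded)
  names(cm) <- paste0("coded_", factors$name)
  out <- cbind(out, cm)
  out$is_center <- apply(abs(coded) < 1e-9, 1, all)
  out$batch <- rep_len(as.character(batch), n)
  attr(out, "factors") <- factors
  class(out) <- c("design_table", "data.frame")
  out
}

#' Extract coded / actual settings from a design table
#' @param design a `design_table`.
#' @return Numeric matrix (runs x factors).
#' @export
coded_matrix <- function(design) {
  f <- design_factors(design)
  m <- as.matrix(design[, paste0("coded_", f$name), drop = FALSE])
  colnames(m) <- f$name
  rownames(m) <- design$run_id
  m
}

#' @rdname coded_matrix
#' @export
actual_matrix <- function(design) {
  f <- design_factors(design)
  m <- as.matrix(design[, f$name, drop = FALSE])
  rownames(m) <- design$run_id
  m
}

#' @rdname coded_matrix
#' @export
design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("design table carries no factor set")
  f
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Design: %d runs (%d center points), %d factors, batches: %s\n",
              nrow(x), sum(x$is_center), nrow(design_factors(x)),
              paste(unique(stats::na.omit(x$batch)), collapse = ", ")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

## log det(X'X); -Inf when singular or not positive definite
.log_det_info <- function(F) {
  d <- determinant(crossprod(F), logarithm = TRUE)
  if (d$sign <= 0 || !is.finite(d$modulus)) return(-Inf)
  as.numeric(d$modulus)
}

## model-matrix row for one coded point, via precompiled term indices
.term_index <- function(model) {
  idx <- list()
  if (model$intercept) idx[["(Intercept)"]] <- integer(0)
  for (f in model$main) idx[[f]] <- match(f, model$factors)
  for (tm in c(model$interactions, model$extra))
    idx[[paste(tm, collapse = ":")]] <- match(tm, model$factors)
  idx
}

.mm_row <- function(x, tidx) {
  vapply(tidx, function(ii) if (length(ii) == 0) 1 else prod(x[ii]), 0)
}

#' D-optimal design by coordinate exchange
#'
#' Searches for the `n_runs`-point design maximizing `det(X'X)` of the
#' information matrix for the requested interaction model, using multi-start
#' coordinate exchange: starting from a random candidate subset, each run's
#' coordinates are cycled through the candidate levels of that factor and an
#' exchange is kept whenever it increases the determinant, until a full pass
#' makes no improvement. The best design over `n_starts` restarts is
#' returned. Results are deterministic for a given `seed`; ties are broken by
#' the first design found.
#'
#' @param factors a [factor_set()].
#' @param model a [model_spec()]; defaults to the full two-factor
#'   interaction model over `factors`.
#' @param n_runs number of design runs; must be at least the parameter count.
#' @param candidates coded candidate matrix, default [candidate_set()] with
#'   3 levels per factor.
#' @param n_starts number of random restarts (default 20).
#' @param seed integer RNG seed (default 0).
#' @param max_passes safety cap on exchange passes per start.
#' @return A `design_table` with attributes `log_det` (the achieved
#'   log-determinant) and `model`.
#' @export
#' @examples
#' f <- factor_set(c("A", "B"), c(0, 0), c(1, 1))
#' d <- d_optimal_design(f, n_runs = 4, seed = 1)
#' attr(d, "log_det")   # log det of the 2^2 factorial: log(4^4)
d_optimal_design <- function(factors, model = model_spec(factors),
                             n_runs, candidates = candidate_set(factors),
                             n_starts = 20, seed = 0, max_passes = 100) {
  p <- n_parameters(model)
  if (n_runs < p)
    stop(sprintf(
      "n_runs (%d) < number of model parameters (%d): information matrix would be singular",
      n_runs, p))
  candidates <- .as_factor_matrix(candidates, factors)
  k <- ncol(candidates)
  levels <- lapply(seq_len(k), function(j) sort(unique(candidates[, j])))
  tidx <- .term_index(model)

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  best_X <- NULL
  best_ld <- -Inf
  for (s in seq_len(n_starts)) {
    ## random nonsingular start (retry a few times, then take what we have)
    X <- NULL
    for (try in 1:25) {
      rows <- sample.int(nrow(candidates), n_runs,
                         replace = n_runs > nrow(candidates))
      X <- candidates[rows, , drop = FALSE]
      F <- t(apply(X, 1, .mm_row, tidx = tidx))
      ld <- .log_det_info(F)
      if (is.finite(ld)) break
    }
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (i in seq_len(n_runs)) {
        for (j in seq_len(k)) {
          cur <- X[i, j]
          for (lev in levels[[j]]) {
            if (lev == cur) next
            xi <- X[i, ]; xi[j] <- lev
            Fi <- F; Fi[i, ] <- .mm_row(xi, tidx)
            ld2 <- .log_det_info(Fi)
            if (ld2 > ld + 1e-12) {
              X[i, j] <- lev; F <- Fi; ld <- ld2
              cur <- lev
              improved <- TRUE
            }
          }
        }
      }
      if (!improved) break
    }
    if (ld > best_ld + 1e-12) {
      best_ld <- ld
      best_X <- X
    }
  }
  if (!is.finite(best_ld))
    stop("no nonsingular design found: candidates do not span the model space")
  ## canonical row order for reproducibility across equivalent optima
  ord <- do.call(order, as.data.frame(best_X))
  des <- design_table(best_X[ord, , drop = FALSE], factors)
  attr(des, "log_det") <- best_ld
  attr(des, "model") <- model
  des
}

#' Score a design: log-determinant and G-efficiency
#'
#' G-efficiency compares the worst-case scaled prediction variance over the
#' candidate region with its theoretical floor: `Geff = 100 p / d_max`, where
#' `d_max = max_x n x'(X'X)^{-1} x` over candidate points. 100% is attained
#' by orthogonal saturated designs (e.g. the 2^2 factorial for the
#' main+interaction model).
#'
#' @param design a `design_table`.
#' @param model a [model_spec()].
#' @param candidates coded candidate matrix over which the worst-case
#'   prediction variance is sought.
#' @return For `g_efficiency`, a percent in (0, 100]. For `design_score`, a
#'   list with `log_det`, `g_efficiency`, `n_runs`, `p`.
#' @export
g_efficiency <- function(design, model,
                         candidates = candidate_set(design_factors(design))) {
  F <- build_model_matrix(design, model)
  p <- n_parameters(model)
  n <- nrow(F)
  M <- crossprod(F)
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular information matrix: design does not support the model"))
  Fc <- build_model_matrix(.as_factor_matrix(candidates,
                                             design_factors(design)), model)
  d <- n * rowSums((Fc %*% Minv) * Fc)
  100 * p / max(d)
}

#' @rdname g_efficiency
#' @export
design_score <- function(design, model,
                         candidates = candidate_set(design_factors(design))) {
  F <- build_model_matrix(design, model)
  list(log_det = .log_det_info(F),
       g_efficiency = g_efficiency(design, model, candidates),
       n_runs = nrow(F), p = n_parameters(model))
}

#' Append replicated center points
#'
#' Center points set every factor to its mid concentration (coded 0). They
#' replicate a single condition, providing the pure-error estimate behind
#' model validity and reproducibility, and anchor between-batch
#' normalization.
#'
#' @param design a `design_table`.
#' @param k number of center points to append (>= 0).
#' @return The augmented `design_table`; `log_det` attribute is refreshed
#'   when a model is attached.
#' @export
add_center_points <- function(design, k) {
  stopifnot(k >= 0)
  if (k == 0) return(design)
  f <- design_factors(design)
  model <- attr(design, "model")
  coded <- rbind(coded_matrix(design),
                 matrix(0, k, nrow(f), dimnames = list(NULL, f$name)))
  ids <- c(design$run_id, sprintf("C%02d", seq_len(k)))
  out <- design_table(coded, f, run_id = ids,
                      batch = c(design$batch, rep(NA_character_, k)))
  attr(out, "model") <- model
  if (!is.null(model))
    attr(out, "log_det") <- .log_det_info(build_model_matrix(out, model))
  out
}

#' Assign runs to experimental batches
#'
#' Splits the campaign into `n_batches` batches run at different times.
#' Center points are spread round-robin so every batch holds at least one
#' (required by center-point normalization); the remaining runs are shuffled
#' (seeded, deterministic) and dealt round-robin.
#'
#' @param design a `design_table`.
#' @param n_batches number of batches (>= 1).
#' @param seed integer seed for the shuffle.
#' @return The `design_table` with a filled `batch` column (`B1`, `B2`, ...).
#' @export
assign_batches <- function(design, n_batches, seed = 0) {
  stopifnot(n_batches >= 1)
  if (n_batches > 1 && sum(design$is_center) < n_batches)
    stop(sprintf("need at least one center point per batch (%d center, %d batches)",
                 sum(design$is_center), n_batches))
  labels <- sprintf("B%d", seq_len(n_batches))
  batch <- rep(NA_character_, nrow(design))
  ctr <- which(design$is_center)
  batch[ctr] <- rep_len(labels, length(ctr))
  rest <- which(!design$is_center)
  if (length(rest) > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
    rest <- rest[sample.int(length(rest))]
    batch[rest] <- rep_len(labels, length(rest))
  }
  design$batch <- batch
  design
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
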