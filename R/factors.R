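#' Define a set of medium-additive factors
#'
#' A factor set describes the medium additives varied in a bioreactor
#' campaign: one row per additive with its low and high concentration and
#' units. Coded design levels in \[-1, +1\] map onto the concentration range
#' by an affine (or, optionally, log-linear) transformation.
#'
#' @param name character vector of unique factor names.
#' @param low,high numeric vectors of concentration limits, `low < high`,
#'   both non-negative. Units are factor-specific (e.g. µg/ml for heparin,
#'   mg/ml for the polymers).
#' @param units character vector of unit labels (recycled).
#' @param spacing `"linear"` (default) or `"log"` per factor. Log spacing
#'   requires `low > 0`.
#' @return A `factor_set` data.frame with columns `name`, `low`, `high`,
#'   `units`, `spacing`.
#' @seealso [default_factors()] for the five-additive screening set,
#'   [coded_to_actual()] for the level mapping.
#' @export
#' @examples
#' factor_set(c("PEG", "HS"), low = c(0, 0), high = c(10, 0.2),
#'            units = c("mg/ml", "ug/ml"))
factor_set <- function(name, low, high, units = "", spacing = "linear") {
  stopifnot(length(name) >= 1, length(low) == length(name),
            length(high) == length(name))
  name <- as.character(name)
  if (anyDuplicated(name)) stop("factor names must be unique")
  low <- as.numeric(low); high <- as.numeric(high)
  if (any(!is.finite(low)) || any(!is.finite(high)))
    stop("factor limits must be finite")
  if (any(low < 0)) stop("concentrations must be >= 0")
  if (any(low >= high)) stop("'low' must be strictly less than 'high'")
  spacing <- rep_len(match.arg(spacing, c("linear", "log"), several.ok = TRUE),
                     length(name))
  if (any(spacing == "log" & low <= 0))
    stop("log spacing requires low > 0")
  out <- data.frame(name = name, low = low, high = high,
                    units = rep_len(as.character(units), length(name)),
                    spacing = spacing, stringsAsFactors = FALSE)
  class(out) <- c("factor_set", "data.frame")
  out
}

#' Default five-additive factor set
#'
#' The five high-molecular-weight additives screened for iPSC aggregate
#' culture: dextran sulfate (DS), heparin sodium salt (HS), poly(vinyl
#' alcohol) (PVA), Pluronic F68 (PA) and polyethylene glycol (PEG). The low
#' level of every factor is zero, so the all-low corner is the unsupplemented
#' basal medium. The high levels shipped here are placeholder ranges anchored
#' to typical literature concentrations (e.g. 1 mg/ml PVA, 10 mg/ml PEG);
#' edit them, or load your own table with [read_factors()], before designing
#' a real campaign.
#'
#' @return A [factor_set()] with five rows.
#' @export
default_factors <- function() {
  factor_set(
    name  = c("DS", "HS", "PVA", "PA", "PEG"),
    low   = c(0, 0, 0, 0, 0),
    high  = c(0.1, 0.2, 1, 1, 10),
    units = c("mg/ml", "ug/ml", "mg/ml", "mg/ml", "mg/ml")
  )
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("Factor set: %d medium additives\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Map coded levels to actual concentrations (and back)
#'
#' Coded level -1 corresponds to `low`, +1 to `high`; with linear spacing the
#' map is `actual = low + (coded + 1)/2 * (high - low)`, with log spacing the
#' same interpolation is applied to log-concentration. The two functions are
#' exact inverses.
#'
#' @param coded,actual numeric matrix (runs x factors) or vector of length
#'   `nrow(factors)`.
#' @param factors a [factor_set()].
#' @return Matrix (or vector) of the same shape in the other scale.
#' @export
coded_to_actual <- function(coded, factors) {
  coded <- .as_factor_matrix(coded, factors)
  out <- coded
  for (j in seq_len(nrow(factors))) {
    f <- factors[j, ]
    t <- (coded[, j] + 1) / 2
    out[, j] <- if (f$spacing == "log")
      exp(log(f$low) + t * (log(f$high) - log(f$low)))
    else f$low + t * (f$high - f$low)
  }
  out
}

#' @rdname coded_to_actual
#' @export
actual_to_coded <- function(actual, factors) {
  actual <- .as_factor_matrix(actual, factors)
  out <- actual
  for (j in seq_len(nrow(factors))) {
    f <- factors[j, ]
    t <- if (f$spacing == "log")
      (log(actual[, j]) - log(f$low)) / (log(f$high) - log(f$low))
    else (actual[, j] - f$low) / (f$high - f$low)
    out[, j] <- 2 * t - 1
  }
  out
}

.as_factor_matrix <- function(x, factors) {
  k <- nrow(factors)
  if (is.null(dim(x))) x <- matrix(x, ncol = k, byrow = FALSE,
                                   dimnames = list(NULL, factors$name))
  if (ncol(x) != k) stop("expected ", k, " factor columns")
  x <- as.matrix(x)
  colnames(x) <- factors$name
  x
}
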