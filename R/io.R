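#' Read and write the pipeline's tabular formats
#'
#' All tables are plain UTF-8 CSV with a header row. `factors.csv` has
#' columns `name,low,high,units` (optional `spacing`); `design.csv` carries
#' `run_id`, one actual-concentration column per factor, `coded_<factor>`
#' columns, `is_center` and `batch`; `series.csv` is long format with
#' `run_id,day,measurement_type,replicate,value` where `measurement_type`
#' is `count`, `diameter` or `viability`.
#'
#' @param path file path.
#' @return `read_factors`: a [factor_set()].
#' @export
read_factors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "low", "high")
  if (!all(need %in% names(df)))
    stop("factors.csv must have columns name, low, high")
  factor_set(df$name, df$low, df$high,
             units = df$units %||% "",
             spacing = df$spacing %||% "linear")
}

#' @rdname read_factors
#' @param factors a [factor_set()].
#' @export
write_factors <- function(factors, path) {
  utils::write.csv(as.data.frame(unclass(factors)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_factors
#' @param design a `design_table`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_factors
#' @export
read_design <- function(path, factors) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  coded_cols <- paste0("coded_", factors$name)
  if (!all(coded_cols %in% names(df)))
    stop("design.csv lacks coded_<factor> columns for the given factor set")
  out <- design_table(as.matrix(df[, coded_cols]), factors,
                      run_id = df$run_id,
                      batch = df$batch %||% NA_character_)
  out
}

#' @rdname read_factors
#' @param series a named list of [reactor_series()].
#' @export
write_series <- function(series, path) {
  rows <- lapply(series, function(s) {
    out <- list()
    for (i in seq_along(s$days)) {
      d <- s$days[i]
      if (length(s$counts[[i]]))
        out[[length(out) + 1]] <- data.frame(
          run_id = s$run_id, day = d, measurement_type = "count",
          replicate = seq_along(s$counts[[i]]), value = s$counts[[i]])
      if (length(s$diameters[[i]]))
        out[[length(out) + 1]] <- data.frame(
          run_id = s$run_id, day = d, measurement_type = "diameter",
          replicate = seq_along(s$diameters[[i]]), value = s$diameters[[i]])
      if (!is.null(s$viability) && is.finite(s$viability[i]))
        out[[length(out) + 1]] <- data.frame(
          run_id = s$run_id, day = d, measurement_type = "viability",
          replicate = 1L, value = s$viability[i])
    }
    do.call(rbind, out)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_factors
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "day", "measurement_type", "value")
  if (!all(need %in% names(df)))
    stop("series.csv must have columns run_id, day, measurement_type, value")
  out <- lapply(split(df, df$run_id), function(d) {
    days <- sort(unique(d$day))
    get <- function(type) lapply(days, function(dd) {
      v <- d$value[d$day == dd & d$measurement_type == type]
      if (length(v)) v else NULL
    })
    vb <- vapply(days, function(dd) {
      v <- d$value[d$day == dd & d$measurement_type == "viability"]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    reactor_series(d$run_id[1], days, get("count"), get("diameter"),
                   viability = if (all(is.na(vb))) NULL else vb)
  })
  out[unique(df$run_id)]
}

#' @rdname read_factors
#' @export
read_responses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize fitted models to JSON
#'
#' One entry per response: coefficients with confidence bounds, the four
#' quality metrics and the transform tag.
#'
#' @param fit a `doe_fit` from [fit_response_models()].
#' @param path output path.
#' @export
write_models_json <- function(fit, path) {
  out <- lapply(fit$models, function(m) list(
    response = m$response, transform = m$transform,
    terms = m$terms, coef = as.list(m$coef),
    ci_lower = as.list(m$ci[, 1]), ci_upper = as.list(m$ci[, 2]),
    r2 = m$r2, q2 = m$q2, validity = m$validity,
    reproducibility = m$reproducibility, df_res = m$df_res))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read desirability criteria from YAML
#'
#' The file maps response names to goal/limits/target/weight, e.g.
#' ```yaml
#' doubling_time: {goal: minimize, low: 1.0, high: 2.5}
#' OCT4_flow:     {goal: maximize, low: 80, high: 95, weight: 2}
#' ```
#'
#' @param path YAML file path.
#' @return List of [criterion()] objects.
#' @export
read_criteria <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(names(y), function(nm) {
    cr <- y[[nm]]
    criterion(nm, goal = cr$goal,
              low = cr$low %||% -Inf, high = cr$high %||% Inf,
              target = cr$target, weight = cr$weight %||% 1)
  })
}
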