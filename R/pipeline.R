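#' Validate pipeline input tables
#'
#' Schema and invariant checks on the tabular inputs before any analysis
#' runs: duplicate run identifiers, coded levels outside the box, coded vs
#' actual inconsistencies, nonpositive counts or diameters, non-increasing
#' days, missing diameter days (the stability statistic will be undefined),
#' percentages outside 0-100, and response rows without a design run.
#'
#' @param factors optional [factor_set()].
#' @param design optional `design_table`.
#' @param series optional list of [reactor_series()].
#' @param responses optional response data.frame.
#' @return data.frame of diagnostics (`table`, `severity`, `message`);
#'   zero rows when everything checks out.
#' @export
validate_tables <- function(factors = NULL, design = NULL, series = NULL,
                            responses = NULL) {
  out <- list()
  note <- function(table, severity, message)
    out[[length(out) + 1]] <<- data.frame(table = table, severity = severity,
                                          message = message)
  if (!is.null(design)) {
    if (anyDuplicated(design$run_id))
      note("design", "error", sprintf("duplicate run_id: %s",
        paste(unique(design$run_id[duplicated(design$run_id)]),
              collapse = ", ")))
    cm <- coded_matrix(design)
    if (any(abs(cm) > 1 + 1e-9))
      note("design", "error", "coded levels outside [-1, +1]")
    f <- design_factors(design)
    back <- coded_to_actual(cm, f)
    if (max(abs(back - actual_matrix(design))) > 1e-6 * max(f$high))
      note("design", "error", "coded and actual settings disagree")
    if (any(design$is_center & rowSums(abs(cm)) > 1e-9))
      note("design", "error", "center-flagged row with nonzero coded levels")
  }
  if (!is.null(series)) {
    for (s in series) {
      if (any(diff(s$days) <= 0))
        note("series", "error",
             sprintf("run %s: days not strictly increasing", s$run_id))
      for (i in seq_along(s$days)) {
        if (length(s$counts[[i]]) && any(s$counts[[i]] <= 0))
          note("series", "error",
               sprintf("run %s day %d: nonpositive count",
                       s$run_id, s$days[i]))
        if (length(s$diameters[[i]]) && any(s$diameters[[i]] <= 0))
          note("series", "error",
               sprintf("run %s day %d: nonpositive diameter",
                       s$run_id, s$days[i]))
      }
      if (all(vapply(s$diameters, length, 0L) == 0))
        note("series", "warning",
             sprintf("run %s: no diameter measurements; stability undefined",
                     s$run_id))
    }
    if (!is.null(design)) {
      missing <- setdiff(design$run_id,
                         vapply(series, `[[`, "", "run_id"))
      if (length(missing))
        note("series", "error", sprintf("design runs without series: %s",
                                        paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(responses)) {
    if (!is.null(design)) {
      extra <- setdiff(responses$run_id, design$run_id)
      if (length(extra))
        note("responses", "error",
             sprintf("responses for unknown runs: %s",
                     paste(extra, collapse = ", ")))
    }
    pct_cols <- intersect(names(responses),
                          c("viability", "OCT4_flow", "SOX2_flow",
                            "SSEA4_flow", "TRA160_flow"))
    for (col in pct_cols) {
      v <- responses[[col]]
      if (any(is.finite(v) & (v < 0 | v > 100)))
        note("responses", "error",
             sprintf("'%s' outside 0-100%%", col))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(table = character(), severity = character(),
                  message = character())
}

#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] consumes, with every
#' field at its default: the five-additive factor set, a generated 19-run
#' design (16 D-optimal + 3 center, 2 batches), synthetic series from the
#' default truth, default geometry, the negative-log transform on the two
#' skewed flow markers, and no optimization criteria. Override fields by
#' passing a partial list (or YAML file) to [run_pipeline()].
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return Named list.
#' @export
default_config <- function(out_dir = tempfile("aggdoe_"), seed = 0) {
  list(
    out_dir = out_dir,
    seed = seed,
    factors = NULL,          # path to factors.csv, or NULL for defaults
    design = NULL,           # path to design.csv, or NULL to generate
    n_runs = 16, n_center = 3, n_batches = 2,
    series = NULL,           # path to series.csv, or NULL to simulate
    responses = NULL,        # path to responses.csv (endpoint assays)
    geometry = list(cell_diameter = 10, packing_density = 0.64,
                    horizon_days = 3),
    transforms = list(OCT4_flow = "neglog", TRA160_flow = "neglog"),
    normalize = TRUE,
    criteria = NULL          # path to criteria.yaml, or a list of criterion
  )
}

#' Run the full design-to-optimization pipeline
#'
#' Orchestrates the stages end to end: (1) load or generate the design;
#' (2) load reactor series or simulate them; (3) compute the
#' kinetics/geometry responses and merge endpoint assays; (4) normalize to
#' center points and fit the interaction models with quality metrics;
#' (5) response correlation matrix; (6) optional desirability optimization.
#' Every artifact is written to `out_dir` (`design.csv`, `series.csv`,
#' `responses.csv`, `models.json`, `corr.csv`, `setpoint.json`,
#' `report.md`) together with `manifest.json` recording the package
#' version, seeds, configuration hash and output checksums; reruns with
#' identical inputs are bit-identical.
#'
#' @param config a list as from [default_config()] (partial lists are
#'   filled with defaults) or the path to a YAML file with the same fields.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the design, series, responses, fits,
#'   correlations, setpoint (or NULL) and the manifest.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  say <- function(...) if (!quiet) message("[aggdoe] ", sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  op <- function(f) file.path(config$out_dir, f)

  factors <- if (is.null(config$factors)) default_factors()
             else read_factors(config$factors)
  model <- model_spec(factors)

  say("stage 1/6: design")
  design <- if (is.null(config$design)) {
    default_campaign_design(factors, config$n_runs, config$n_center,
                            config$n_batches, seed = config$seed)
  } else read_design(config$design, factors)
  write_design(design, op("design.csv"))

  geom <- do.call(geometry_constants, config$geometry)
  truth <- NULL
  say("stage 2/6: series (%s)",
      if (is.null(config$series)) "simulated" else "loaded")
  if (is.null(config$series)) {
    truth <- sim_truth(factors = factors, model = model, geom = geom)
    camp <- simulate_campaign(design, truth, seed = config$seed)
    series <- camp$series
    responses <- camp$responses
  } else {
    series <- read_series(config$series)
    responses <- NULL
  }
  diag <- validate_tables(factors, design, series, responses)
  if (any(diag$severity == "error")) {
    print(diag)
    stop("input validation failed (see diagnostics above)")
  }
  write_series(series, op("series.csv"))

  say("stage 3/6: kinetics and aggregate metrics")
  if (is.null(responses)) {
    responses <- series_responses(series, geom)
    if (!is.null(config$responses)) {
      extra <- read_responses(config$responses)
      responses <- merge(responses, extra, by = "run_id", sort = FALSE)
    }
  }
  utils::write.csv(responses, op("responses.csv"), row.names = FALSE)

  say("stage 4/6: interaction models")
  transforms <- unlist(config$transforms)
  transforms <- transforms[names(transforms) %in% names(responses)]
  fits <- fit_response_models(design, responses, model,
                              transforms = transforms,
                              normalize = isTRUE(config$normalize))
  write_models_json(fits, op("models.json"))

  say("stage 5/6: correlations")
  corr <- correlation_matrix(fits$responses)
  utils::write.csv(round(corr$r, 6), op("corr.csv"))

  setpoint <- NULL
  if (!is.null(config$criteria)) {
    say("stage 6/6: desirability optimization")
    criteria <- if (is.character(config$criteria))
      read_criteria(config$criteria) else config$criteria
    setpoint <- optimize_setpoint(fits, criteria, seed = config$seed)
    jsonlite::write_json(list(
      coded = as.list(setpoint$coded),
      actual = as.list(setpoint$actual),
      desirability = setpoint$desirability,
      criteria = setpoint$criteria,
      factor_contributions = as.data.frame(setpoint$factor_contributions)),
      op("setpoint.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else say("stage 6/6: no criteria; skipping optimization")

  .write_report(op("report.md"), design, fits, setpoint)
  manifest <- .write_manifest(config, op("manifest.json"))
  invisible(list(design = design, series = series,
                 responses = fits$responses, fits = fits, corr = corr,
                 setpoint = setpoint, manifest = manifest))
}

.write_report <- function(path, design, fits, setpoint) {
  md <- c("# Campaign report", "",
          sprintf("%d runs (%d center points) in %d batches; %d responses modeled.",
                  nrow(design), sum(design$is_center),
                  length(unique(stats::na.omit(design$batch))),
                  length(fits$models)),
          "", "## Model quality", "",
          .md_table(round_df(metric_table(fits), 3)))
  md <- c(md, "", "## Coefficients (coded units)", "")
  for (m in fits$models) {
    tab <- data.frame(term = m$terms, coef = m$coef,
                      lower = m$ci[, 1], upper = m$ci[, 2])
    md <- c(md, sprintf("### %s (%s)", m$response, m$transform), "",
            .md_table(round_df(tab, 4)), "")
  }
  if (!is.null(setpoint)) {
    md <- c(md, "## Optimized setpoint", "",
            sprintf("Overall desirability D = %.3f", setpoint$desirability),
            "",
            .md_table(round_df(data.frame(factor = names(setpoint$coded),
                                          coded = setpoint$coded,
                                          actual = setpoint$actual), 4)),
            "", .md_table(round_df(setpoint$criteria, 3)))
  }
  writeLines(md, path)
  invisible(path)
}

round_df <- function(df, digits) {
  for (i in seq_along(df))
    if (is.numeric(df[[i]])) df[[i]] <- round(df[[i]], digits)
  df
}

.md_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(trimws(format(r)), collapse = " | "), " |"))
  c(hdr, sep, rows)
}

.write_manifest <- function(config, path) {
  out_dir <- config$out_dir
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  if (!is.null(config$criteria) && !is.character(config$criteria))
    config$criteria <- lapply(config$criteria, unclass)
  jsonlite::write_json(config[order(names(config))], cfg_file,
                       auto_unbox = TRUE, digits = NA)
  artifacts <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, artifacts))
  names(sums) <- artifacts
  manifest <- list(
    package = "aggdoe",
    version = as.character(utils::packageVersion("aggdoe")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(sums))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
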