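#' Ground truth for a synthetic bioreactor campaign
#'
#' Encodes everything the generator needs to produce a campaign with known
#' answers: how the specific growth rate and the aggregate fusion rate
#' depend on the coded factor settings, the coefficient structure behind
#' every endpoint response, and the measurement-noise levels. Defaults
#' describe a realistic five-additive screening campaign: seeding density
#' 1.1e5 cells/ml, baseline growth 0.5/day (doubling time 1.4 days),
#' lognormal day-1 aggregate diameters around 65 µm, a baseline fusion rate
#' of 0.1 events/aggregate/day suppressed by heparin and PEG, triplicate
#' counts with 10% CV, and >= 30 aggregate diameters measured per day.
#'
#' Flow-marker frequencies are generated on the logit scale and
#' back-transformed to percent, so they respect the 0-100 bounds and give
#' the negative-log transform path something real to normalize; qPCR levels
#' and viability are linear in the coded model terms with additive Gaussian
#' noise. Multiplicative batch offsets (lognormal) are applied to the
#' endpoint assay responses, which is exactly the drift the center-point
#' normalization removes.
#'
#' @param factors a [factor_set()] (default [default_factors()]).
#' @param model a [model_spec()] over those factors.
#' @param K0 baseline specific growth rate, 1/day.
#' @param beta_K named coefficients (over non-intercept model terms) of the
#'   growth rate.
#' @param N0 seeding density, cells/ml.
#' @param fusion_base fusion rate at the center point,
#'   events/aggregate/day.
#' @param fusion_beta named log-scale coefficients of the fusion rate.
#' @param frag_rate fragmentation (binary split) rate,
#'   events/aggregate/day.
#' @param n_aggregates initial aggregate population per reactor.
#' @param init_diameter median day-1 aggregate diameter, µm.
#' @param n_measure diameters sampled per day (>= 30 mirrors practice).
#' @param count_cv lognormal CV of replicate counts.
#' @param diameter_sdlog lognormal sigma of the initial diameter spread.
#' @param marker_sd logit-scale SD of marker noise.
#' @param batch_sdlog lognormal sigma of per-batch assay offsets.
#' @param response_truth named list of endpoint response definitions, each
#'   `list(beta = <named coefficients over model terms>, scale = "identity"
#'   or "logit", noise_sd = <SD on the generating scale>)`.
#' @param geom [geometry_constants()] used downstream.
#' @param days culture days simulated (default 0:4).
#' @return A `sim_truth` object.
#' @export
sim_truth <- function(factors = default_factors(),
                      model = model_spec(factors),
                      K0 = 0.5,
                      beta_K = c(DS = -0.03, HS = 0.02, PVA = 0.03,
                                 PA = 0.04, PEG = 0.05,
                                 "HS:PEG" = 0.02, "PA:PEG" = 0.03),
                      N0 = 1.1e5,
                      fusion_base = 0.1,
                      fusion_beta = c(DS = -0.3, HS = -0.5, PEG = -0.8,
                                      "HS:PEG" = -0.4),
                      frag_rate = 0.01,
                      n_aggregates = 150,
                      init_diameter = 65,
                      n_measure = 30,
                      count_cv = 0.10,
                      diameter_sdlog = 0.15,
                      marker_sd = 0.15,
                      batch_sdlog = 0.05,
                      response_truth = default_response_truth(),
                      geom = geometry_constants(),
                      days = 0:4) {
  beta_K <- .check_beta(beta_K, model, "beta_K")
  fusion_beta <- .check_beta(fusion_beta, model, "fusion_beta")
  stopifnot(K0 > 0, N0 > 0, fusion_base >= 0, frag_rate >= 0,
            count_cv >= 0, diameter_sdlog >= 0, marker_sd >= 0,
            batch_sdlog >= 0, n_aggregates >= 2, n_measure >= 1,
            length(days) >= 2)
  for (nm in names(response_truth)) {
    rt <- response_truth[[nm]]
    response_truth[[nm]]$beta <- .check_beta(rt$beta, model, nm,
                                             allow_intercept = TRUE)
    stopifnot(rt$scale %in% c("identity", "logit"), rt$noise_sd >= 0)
  }
  structure(list(factors = factors, model = model, K0 = K0,
                 beta_K = beta_K, N0 = N0, fusion_base = fusion_base,
                 fusion_beta = fusion_beta, frag_rate = frag_rate,
                 n_aggregates = n_aggregates, init_diameter = init_diameter,
                 n_measure = n_measure, count_cv = count_cv,
                 diameter_sdlog = diameter_sdlog, marker_sd = marker_sd,
                 batch_sdlog = batch_sdlog, response_truth = response_truth,
                 geom = geom, days = as.integer(days)),
            class = "sim_truth")
}

.check_beta <- function(beta, model, what, allow_intercept = FALSE) {
  valid <- if (allow_intercept) model$terms
           else setdiff(model$terms, "(Intercept)")
  bad <- setdiff(names(beta), valid)
  if (length(bad))
    stop(what, ": coefficients for terms not in the model: ",
         paste(bad, collapse = ", "))
  beta
}

#' @rdname sim_truth
#' @export
default_response_truth <- function() {
  list(
    OCT4_flow = list(scale = "logit", noise_sd = 0.15,
      beta = c("(Intercept)" = 2.2, HS = 0.3, PEG = 0.4, "HS:PEG" = 0.25)),
    SOX2_flow = list(scale = "logit", noise_sd = 0.15,
      beta = c("(Intercept)" = 2.5, PEG = 0.3, PVA = 0.2)),
    SSEA4_flow = list(scale = "logit", noise_sd = 0.15,
      beta = c("(Intercept)" = 2.8, HS = 0.25, DS = -0.2)),
    TRA160_flow = list(scale = "logit", noise_sd = 0.15,
      beta = c("(Intercept)" = 2.0, PEG = 0.35, DS = -0.2, "HS:PEG" = 0.2)),
    NANOG_qpcr = list(scale = "identity", noise_sd = 50, batch_effect = TRUE,
      beta = c("(Intercept)" = 1000, DS = -80, HS = 120, PVA = 60,
               PEG = 150, "HS:PEG" = 100)),
    OCT4_qpcr = list(scale = "identity", noise_sd = 50, batch_effect = TRUE,
      beta = c("(Intercept)" = 900, HS = 100, PVA = 50, PEG = 130,
               "HS:PEG" = 80)),
    SOX2_qpcr = list(scale = "identity", noise_sd = 50, batch_effect = TRUE,
      beta = c("(Intercept)" = 1100, DS = -60, PA = 70, PEG = 90,
               "PA:PEG" = 60)),
    viability = list(scale = "identity", noise_sd = 1,
      beta = c("(Intercept)" = 92, DS = -1, PA = 1.5, PEG = 1))
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic campaign truth: %d factors, K0 = %.2f/day, fusion %.3g/agg/day at center,\n  %d endpoint responses, count CV %.0f%%, diameter sdlog %.2f\n",
    length(x$model$factors), x$K0, x$fusion_base,
    length(x$response_truth), 100 * x$count_cv, x$diameter_sdlog))
  invisible(x)
}

## linear predictor over model terms at coded x
.truth_predictor <- function(x, beta, model) {
  row <- .mm_row(x, .term_index(model))
  names(row) <- model$terms
  sum(beta * row[names(beta)])
}

#' Simulate one bioreactor run
#'
#' Forward model of a single reactor at coded settings `x`: cells grow
#' exponentially at `K(x) = K0 + x'beta_K` (counts observed in triplicate
#' with lognormal noise, mean-unbiased); the aggregate population starts on
#' day 1 as a lognormal diameter distribution and each subsequent day grows
#' in volume by `exp(K)`, then suffers a Poisson number of pairwise fusions
#' (two aggregates merge, volumes add, sphere-equivalent diameter
#' recomputed) and binary fragmentations (one aggregate splits in half). A
#' fixed number of diameters is sampled per day. Bit-identical output for a
#' given seed.
#'
#' @param x coded factor settings (vector over the truth's factors).
#' @param truth a [sim_truth()].
#' @param seed integer seed.
#' @param viability_mean endpoint viability percent recorded for this run
#'   (default 95).
#' @return A [reactor_series()].
#' @export
simulate_reactor <- function(x, truth, seed = 0, viability_mean = 95) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  model <- truth$model
  K <- truth$K0 + .truth_predictor(x, truth$beta_K, model)
  lam_f <- truth$fusion_base *
    exp(.truth_predictor(x, truth$fusion_beta, model))
  days <- truth$days

  ## triplicate counts, lognormal with exact mean N0 e^{Kt}
  s <- sqrt(log(1 + truth$count_cv^2))
  counts <- lapply(days, function(t) {
    mu <- truth$N0 * exp(K * t)
    if (s == 0) rep(mu, 3)
    else stats::rlnorm(3, meanlog = log(mu) - s^2 / 2, sdlog = s)
  })

  ## aggregate population from day 1 on
  vol <- NULL
  diameters <- vector("list", length(days))
  for (i in seq_along(days)) {
    t <- days[i]
    if (t < 1) next
    if (is.null(vol)) {
      d0 <- if (truth$diameter_sdlog == 0)
        rep(truth$init_diameter, truth$n_aggregates)
      else stats::rlnorm(truth$n_aggregates, log(truth$init_diameter),
                         truth$diameter_sdlog)
      ## grown forward if the first measured day is past day 1
      vol <- sphere_volume(d0 / 2) * exp(K * (t - 1))
    } else {
      vol <- vol * exp(K * (days[i] - days[i - 1]))
      vol <- .fusion_step(vol, lam_f * (days[i] - days[i - 1]))
      vol <- .fragmentation_step(vol, truth$frag_rate *
                                   (days[i] - days[i - 1]))
    }
    take <- if (length(vol) > truth$n_measure)
      sample.int(length(vol), truth$n_measure) else seq_along(vol)
    diameters[[i]] <- sphere_diameter(vol[take])
  }
  viability <- pmin(100, pmax(0, viability_mean +
    if (truth$marker_sd > 0) stats::rnorm(length(days), 0, 0.5) else 0))
  reactor_series(run_id = "sim", days = days, counts = counts,
                 diameters = diameters, viability = viability)
}

## merge 2*n_f randomly chosen aggregates pairwise; volume is additive and
## cell number is conserved, the count drops by one per event
.fusion_step <- function(vol, lam) {
  n_f <- stats::rpois(1, lam * length(vol))
  n_f <- min(n_f, floor(length(vol) / 2))
  if (n_f == 0) return(vol)
  idx <- sample.int(length(vol), 2 * n_f)
  a <- idx[seq_len(n_f)]; b <- idx[n_f + seq_len(n_f)]
  vol[a] <- vol[a] + vol[b]
  vol[-b]
}

## split randomly chosen aggregates into two equal halves
.fragmentation_step <- function(vol, lam) {
  n_b <- stats::rpois(1, lam * length(vol))
  n_b <- min(n_b, length(vol))
  if (n_b == 0) return(vol)
  idx <- sample.int(length(vol), n_b)
  halves <- vol[idx] / 2
  vol[idx] <- halves
  c(vol, halves)
}

#' Simulate a complete campaign over a design
#'
#' Runs [simulate_reactor()] for every design row (independent seeds derived
#' from `seed`), assembles the kinetics/geometry responses with
#' [series_responses()], generates the endpoint assay responses from the
#' truth's coefficient structure (linear or logit scale, plus noise), and
#' applies multiplicative per-batch offsets to the endpoint responses.
#' Center points share identical settings but draw independent noise.
#'
#' @param design a `design_table` (batches assigned; rows in any order).
#' @param truth a [sim_truth()].
#' @param seed integer master seed.
#' @return A `sim_campaign`: list with `design`, `series` (named list of
#'   [reactor_series()]), `responses` (data.frame) and `truth`.
#' @export
simulate_campaign <- function(design, truth = sim_truth(), seed = 0) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  n <- nrow(design)
  run_seeds <- sample.int(2^30, n + 1)
  X <- coded_matrix(design)
  F <- build_model_matrix(design, truth$model)

  ## endpoint truth means (needed before the series for viability)
  endpoint <- list()
  for (nm in names(truth$response_truth)) {
    rt <- truth$response_truth[[nm]]
    mu <- drop(F[, names(rt$beta), drop = FALSE] %*% rt$beta)
    noise <- if (rt$noise_sd > 0) stats::rnorm(n, 0, rt$noise_sd) else 0
    y <- mu + noise
    if (rt$scale == "logit") y <- 100 * stats::plogis(y)
    endpoint[[nm]] <- y
  }

  series <- vector("list", n)
  for (i in seq_len(n)) {
    s <- simulate_reactor(X[i, ], truth, seed = run_seeds[i],
                          viability_mean = endpoint$viability[i] %||% 95)
    s$run_id <- design$run_id[i]
    series[[i]] <- s
  }
  names(series) <- design$run_id

  responses <- series_responses(series, truth$geom)
  ## the series' viability column is the endpoint measurement already
  for (nm in setdiff(names(endpoint), "viability"))
    responses[[nm]] <- endpoint[[nm]]

  ## per-batch multiplicative assay offsets; only unbounded (non-percent)
  ## endpoint assays drift this way, keeping percentages within 0-100
  if (truth$batch_sdlog > 0 && !anyNA(design$batch)) {
    set.seed(run_seeds[n + 1])
    batches <- unique(design$batch)
    drifted <- names(Filter(function(rt) isTRUE(rt$batch_effect),
                            truth$response_truth))
    for (nm in drifted) {
      fac <- stats::rlnorm(length(batches), 0, truth$batch_sdlog)
      names(fac) <- batches
      responses[[nm]] <- responses[[nm]] * fac[design$batch]
    }
  }
  structure(list(design = design, series = series, responses = responses,
                 truth = truth),
            class = "sim_campaign")
}

#' @export
print.sim_campaign <- function(x, ...) {
  cat(sprintf(
    "Synthetic campaign: %d runs (%d center), %d batches, %d response columns\n",
    nrow(x$design), sum(x$design$is_center),
    length(unique(stats::na.omit(x$design$batch))),
    ncol(x$responses) - 1))
  invisible(x)
}

#' Coefficient recovery rate over repeated synthetic campaigns
#'
#' Simulates `n_seeds` independent campaigns from the same truth, fits the
#' interaction model to every response whose generating scale the fit can
#' match (the linear-scale endpoint assays and the growth rate, whose truth
#' is `beta_K`), and reports the fraction of true nonzero non-intercept
#' coefficients that land inside their fitted 95% confidence intervals.
#' Fits are on the raw (un-normalized) responses: with only three center
#' replicates the batch-normalization scale estimate adds batch-correlated
#' noise that is not part of the regression error model, and the recovery
#' study isolates the estimation machinery.
#'
#' @param design a `design_table`.
#' @param truth a [sim_truth()].
#' @param n_seeds number of simulated campaigns.
#' @param seed master seed; campaign `i` uses `seed + i`.
#' @return Overall coverage fraction, with the per-response breakdown as
#'   attribute `"by_response"` and the number of checks as `"n"`.
#' @export
recovery_rate <- function(design, truth = sim_truth(), n_seeds = 500,
                          seed = 0) {
  targets <- list(growth_rate = truth$beta_K)
  for (nm in names(truth$response_truth)) {
    rt <- truth$response_truth[[nm]]
    if (rt$scale == "identity") targets[[nm]] <- rt$beta
  }
  targets <- lapply(targets, function(b) {
    b <- b[setdiff(names(b), "(Intercept)")]
    b[b != 0]
  })
  hits <- tot <- structure(numeric(length(targets)),
                           names = names(targets))
  for (i in seq_len(n_seeds)) {
    camp <- simulate_campaign(design, truth, seed = seed + i)
    fits <- fit_response_models(design, camp$responses, truth$model,
                                normalize = FALSE)
    for (nm in names(targets)) {
      b <- targets[[nm]]
      ci <- fits$models[[nm]]$ci
      ok <- b >= ci[names(b), 1] & b <= ci[names(b), 2]
      hits[nm] <- hits[nm] + sum(ok)
      tot[nm] <- tot[nm] + length(ok)
    }
  }
  structure(sum(hits) / sum(tot), by_response = hits / tot, n = sum(tot))
}

#' Default campaign design mirroring the study layout
#'
#' 16 D-optimal runs for the full two-factor interaction model over the five
#' additives, plus 3 center points, split over 2 batches: 19 media
#' conditions in total.
#'
#' @param factors a [factor_set()].
#' @param n_runs,n_center,n_batches campaign layout.
#' @param seed design-search and batch-shuffle seed.
#' @return A `design_table`.
#' @export
default_campaign_design <- function(factors = default_factors(),
                                    n_runs = 16, n_center = 3,
                                    n_batches = 2, seed = 0) {
  d <- d_optimal_design(factors, model_spec(factors), n_runs = n_runs,
                        seed = seed)
  d <- add_center_points(d, n_center)
  assign_batches(d, n_batches, seed = seed)
}

#' Write a canned synthetic scenario to disk
#'
#' Generates one of the named scenarios and writes `design.csv`,
#' `series.csv` (long format), `responses.csv` and `truth.json` into `dir`.
#' Scenarios: `"clean"` (low noise, strong signal: every response should fit
#' with R2 > 0.9), `"fusion-heavy"` (4x baseline fusion), `"unstable"`
#' (fragmentation-dominated), `"campaign19"` (the default 19-run, 2-batch,
#' 3-center layout at default noise). Identical `name` and `seed` reproduce
#' identical files.
#'
#' @param name scenario tag.
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
make_fixture <- function(name = c("clean", "fusion-heavy", "unstable",
                                  "campaign19"),
                         seed = 0, dir = tempfile("fixture_")) {
  name <- match.arg(name)
  truth <- switch(name,
    "clean" = sim_truth(count_cv = 0.02, diameter_sdlog = 0.04,
                        marker_sd = 0.05, batch_sdlog = 0.01,
                        n_measure = 100,
                        response_truth = local({
                          rt <- default_response_truth()
                          for (nm in names(rt))
                            rt[[nm]]$noise_sd <- rt[[nm]]$noise_sd / 5
                          rt
                        })),
    "fusion-heavy" = sim_truth(fusion_base = 0.4),
    "unstable" = sim_truth(fusion_base = 0.02, frag_rate = 0.3),
    "campaign19" = sim_truth())
  design <- default_campaign_design(truth$factors, seed = seed)
  camp <- simulate_campaign(design, truth, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(design = file.path(dir, "design.csv"),
             series = file.path(dir, "series.csv"),
             responses = file.path(dir, "responses.csv"),
             truth = file.path(dir, "truth.json"))
  write_design(camp$design, paths["design"])
  write_series(camp$series, paths["series"])
  utils::write.csv(camp$responses, paths["responses"], row.names = FALSE)
  .write_truth_json(truth, paths["truth"])
  invisible(paths)
}

.write_truth_json <- function(truth, path) {
  x <- truth
  x$factors <- as.data.frame(unclass(x$factors))
  x$model <- list(factors = x$model$factors,
                  interactions = lapply(x$model$interactions, identity),
                  extra = x$model$extra, intercept = x$model$intercept)
  x$geom <- unclass(x$geom)
  x$response_truth <- lapply(x$response_truth, function(rt)
    list(scale = rt$scale, noise_sd = rt$noise_sd, beta = as.list(rt$beta)))
  x$beta_K <- as.list(x$beta_K)
  x$fusion_beta <- as.list(x$fusion_beta)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
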