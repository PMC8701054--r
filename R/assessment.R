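#' Assemble a run configuration
#'
#' Bundles everything an end-to-end assessment needs: the summary rows to
#' reconstruct, which categories feed the concentration pool, the age groups
#' with their body weights, the toxicological endpoints, one consumption model
#' per age group, and the simulation settings.
#'
#' @param summaries list of [category_summary()] rows, or a path to a summary
#'   CSV ([read_summary_csv()] format). Defaults to the packaged six-category
#'   acrylamide table.
#' @param pool_categories categories pooled into the concentration
#'   distribution; defaults to whole and ground biscuits, the main exposure
#'   contributors.
#' @param age_groups named list of [age_group()]s.
#' @param endpoints named list of [endpoint()]s.
#' @param consumption named list (one entry per age-group label) of
#'   [lognormal_from_moments()] models, or of lists with `mean`/`sd` (g/day)
#'   or `mu`/`sigma` fields.
#' @param simulation a [simulation_config()].
#' @param lod,loq analytical limits used when `summaries` is a CSV path.
#' @return object of class `run_config`.
#' @export
run_config <- function(summaries = table1_path(),
                       pool_categories = c("Biscuits", "Ground biscuits"),
                       age_groups = default_age_groups(),
                       endpoints = default_endpoints(),
                       consumption,
                       simulation = simulation_config(),
                       lod = 10, loq = 30) {
  if (is.character(summaries)) summaries <- read_summary_csv(summaries, lod = lod, loq = loq)
  stopifnot(length(age_groups) >= 1L, length(endpoints) >= 1L)
  labels <- vapply(age_groups, `[[`, character(1), "label")
  consumption <- lapply(consumption, function(cm) {
    if (inherits(cm, "consumption_model")) return(cm)
    if (!is.null(cm$mean)) return(lognormal_from_moments(cm$mean, cm$sd))
    if (!is.null(cm$mean_g_day)) return(lognormal_from_moments(cm$mean_g_day, cm$sd_g_day))
    if (!is.null(cm$mu)) return(lognormal_from_logscale(cm$mu, cm$sigma))
    stop("consumption entries need mean/sd (or mean_g_day/sd_g_day) or mu/sigma")
  })
  missing_cm <- setdiff(labels, names(consumption))
  if (length(missing_cm)) {
    stop("no consumption model for age group(s): ", paste(missing_cm, collapse = ", "))
  }
  structure(
    list(summaries = summaries, pool_categories = pool_categories,
         age_groups = age_groups, endpoints = endpoints,
         consumption = consumption, simulation = simulation),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' Schema (all blocks optional except `consumption`): `summaries_csv` (path;
#' omitted = packaged table), `lod`, `loq`, `pool_categories` (array),
#' `age_groups` (array of `{label, body_weight}`), `endpoints` (array of
#' `{name, bmdl10, concern_threshold}`), `consumption` (object keyed by
#' age-group label, values `{mean_g_day, sd_g_day}` or `{mu, sigma}`),
#' `simulation` (`{iterations, bootstrap_replicates, noise_sd,
#' censoring_policy, master_seed}`). A packaged example lives at
#' `system.file("extdata", "example_config.json", package = "dietmoe")`; its
#' consumption values are illustrative, not survey estimates.
#'
#' @param path JSON file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  summaries <- if (!is.null(js$summaries_csv)) js$summaries_csv else table1_path()
  lod <- js$lod %||% 10
  loq <- js$loq %||% 30
  ages <- if (is.null(js$age_groups)) default_age_groups() else {
    ag <- lapply(js$age_groups, function(a) age_group(a$label, a$body_weight))
    names(ag) <- vapply(ag, `[[`, character(1), "label")
    ag
  }
  eps <- if (is.null(js$endpoints)) default_endpoints() else {
    ep <- lapply(js$endpoints, function(e) endpoint(e$name, e$bmdl10, e$concern_threshold))
    names(ep) <- vapply(ep, `[[`, character(1), "name")
    ep
  }
  sim <- js$simulation %||% list()
  simulation <- simulation_config(
    iterations = sim$iterations %||% 10000,
    bootstrap_replicates = sim$bootstrap_replicates %||% 1000,
    noise_sd = sim$noise_sd %||% 4,
    censoring_policy = sim$censoring_policy %||% "middle_bound",
    master_seed = sim$master_seed %||% 1L
  )
  if (is.null(js$consumption)) stop("config must provide a consumption block")
  run_config(
    summaries = summaries,
    pool_categories = if (is.null(js$pool_categories)) c("Biscuits", "Ground biscuits")
                      else unlist(js$pool_categories),
    age_groups = ages, endpoints = eps, consumption = js$consumption,
    simulation = simulation, lod = lod, loq = loq
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full probabilistic exposure and MOE assessment
#'
#' Executes the pipeline end to end: reconstruct per-sample data from the
#' summary rows, impute left-censored values under the configured policy,
#' bootstrap the concentration pool with measurement error, Monte Carlo
#' simulate daily exposure per age group, transform to MOE per endpoint, and
#' tabulate concern-threshold probabilities and MOE percentiles. All
#' randomness derives from the simulation's master seed, so a repeated run
#' with the same configuration is identical.
#'
#' @param config a [run_config()] (or path to a JSON config, see
#'   [read_run_config()]).
#' @param seed optional integer overriding the config's master seed.
#' @param verbose emit per-stage progress to stderr.
#' @return object of class `moe_assessment`: list with `observations`, `pool`,
#'   `exposures` (per age group), `moe` (per age group x endpoint), `report`
#'   (data frame: one row per age group x endpoint with `prob_below` and MOE
#'   percentiles 5/25/50/75/95), `config`, `seed`.
#' @export
run_assessment <- function(config, seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  sim <- config$simulation
  if (!is.null(seed)) sim$master_seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) say("[%s] %.2fs elapsed", what, proc.time()[["elapsed"]] - t0)

  subseeds <- derive_seeds(sim$master_seed, 2L)
  policy <- censoring_policy(sim$censoring_policy,
                             lod = config$summaries[[1]]$lod,
                             loq = config$summaries[[1]]$loq)

  observations <- generate_study(config$summaries, seed = subseeds[1])
  stage("reconstruct")

  pool_obs <- observations[observations$category %in% config$pool_categories, , drop = FALSE]
  if (!nrow(pool_obs)) stop("no observations in pool categories: ",
                            paste(config$pool_categories, collapse = ", "))
  pool <- bootstrap_concentration(impute(pool_obs, policy),
                                  replicates = sim$bootstrap_replicates,
                                  noise_sd = sim$noise_sd, seed = subseeds[2])
  stage("bootstrap")

  exposures <- lapply(config$age_groups, function(ag) {
    simulate_exposure(pool, config$consumption[[ag$label]], ag, sim)
  })
  stage("exposure")

  moe <- list()
  rows <- list()
  for (ag in names(exposures)) {
    for (epn in names(config$endpoints)) {
      ep <- config$endpoints[[epn]]
      md <- compute_moe(exposures[[ag]], ep)
      moe[[ag]][[epn]] <- md
      qs <- stats::quantile(md$values[is.finite(md$values)],
                            c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        age_group = ag,
        body_weight_kg = exposures[[ag]]$age_group$body_weight,
        endpoint = ep$name, bmdl10 = ep$bmdl10,
        concern_threshold = ep$concern_threshold,
        prob_below = md$prob_below_threshold,
        moe_p5 = qs[1], moe_p25 = qs[2], moe_p50 = qs[3],
        moe_p75 = qs[4], moe_p95 = qs[5],
        iterations = sim$iterations,
        stringsAsFactors = FALSE
      )
    }
  }
  stage("moe")
  structure(
    list(observations = observations, pool = pool, exposures = exposures,
         moe = moe, report = do.call(rbind, rows), config = config,
         seed = sim$master_seed),
    class = "moe_assessment"
  )
}

#' Write assessment report files
#'
#' Writes `report.json` (seed, simulation settings, per age group x endpoint
#' results), `moe_summary.csv` (the report table), `exposure.csv` (one column
#' of simulated exposures per age group) and `observations.csv` (the
#' reconstructed study) into a directory. Report bodies carry no timestamps,
#' so identical runs produce byte-identical files.
#'
#' @param x a [run_assessment()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "moe_assessment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- x$config$simulation
  payload <- list(
    seed = x$seed,
    simulation = list(iterations = sim$iterations,
                      bootstrap_replicates = sim$bootstrap_replicates,
                      noise_sd = sim$noise_sd,
                      censoring_policy = sim$censoring_policy),
    consumption = lapply(x$config$consumption, function(cm) {
      list(mean_g_day = cm$mean, sd_g_day = cm$sd, mu = cm$mu, sigma = cm$sigma)
    }),
    results = x$report
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(x$report, file.path(dir, "moe_summary.csv"), row.names = FALSE)
  write_exposure_csv(x$exposures, file.path(dir, "exposure.csv"))
  write_observations_csv(x$observations, file.path(dir, "observations.csv"))
  invisible(dir)
}

#' @export
print.moe_assessment <- function(x, ...) {
  cat(sprintf("Probabilistic MOE assessment (seed %d, %d iterations)\n",
              x$seed, x$config$simulation$iterations))
  cat(sprintf("  concentration pool: %d values from %d samples x %d replicates (noise SD %g)\n",
              length(x$pool$values), x$pool$source_n, x$pool$replicates, x$pool$noise_sd))
  df <- x$report
  df$prob_below <- sprintf("%.3f", df$prob_below)
  print(df[, c("age_group", "endpoint", "bmdl10", "concern_threshold",
               "prob_below", "moe_p5", "moe_p50", "moe_p95")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.moe_assessment <- function(object, ...) {
  cat("Reconstructed study:\n")
  for (s in summarize_study(object$observations)) print(s)
  cat(sprintf("Detectable samples: %.0f%%\n\n",
              100 * detectable_fraction(object$observations)))
  print(object)
  invisible(object$report)
}

#' Plot a MOE distribution from an assessment
#'
#' Base-graphics histogram or empirical CDF of the simulated MOE values for
#' one age group and endpoint, with the endpoint's concern threshold marked.
#'
#' @param x a [run_assessment()] result.
#' @param age_group age-group label (default: first).
#' @param endpoint endpoint name (default: first).
#' @param type `"cdf"` or `"hist"`.
#' @param ... passed to the underlying plot function.
#' @return invisibly, the plotted `moe_distribution`.
#' @export
plot.moe_assessment <- function(x, age_group = names(x$moe)[1],
                                endpoint = names(x$moe[[1]])[1],
                                type = c("cdf", "hist"), ...) {
  type <- match.arg(type)
  md <- x$moe[[age_group]][[endpoint]]
  vals <- md$values[is.finite(md$values)]
  main <- sprintf("MOE, %s, %s (BMDL10 = %g)", age_group, md$endpoint$name,
                  md$endpoint$bmdl10)
  if (type == "hist") {
    graphics::hist(vals, breaks = 50, main = main, xlab = "MOE", ...)
  } else {
    graphics::plot(stats::ecdf(vals), main = main, xlab = "MOE",
                   ylab = "cumulative probability", ...)
  }
  graphics::abline(v = md$endpoint$concern_threshold, lty = 2)
  invisible(md)
}
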