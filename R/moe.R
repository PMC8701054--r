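# single source of the mg -> ng conversion used by the MOE ratio
NG_PER_MG <- 1e6

#' Toxicological endpoint
#'
#' A benchmark-dose lower bound (BMDL10, mg/kg bw/day) together with the MOE
#' concern threshold conventionally applied to it: MOE above 125 indicates low
#' neurotoxic concern, MOE above 10,000 low carcinogenic concern.
#'
#' @param name endpoint name.
#' @param bmdl10 BMDL10, mg/kg bw/day (> 0).
#' @param concern_threshold MOE value below which the endpoint is of concern.
#' @return object of class `endpoint`.
#' @export
endpoint <- function(name, bmdl10, concern_threshold) {
  stopifnot(length(name) == 1L, is.numeric(bmdl10), is.numeric(concern_threshold))
  if (bmdl10 <= 0) stop("bmdl10 must be positive")
  if (concern_threshold <= 0) stop("concern_threshold must be positive")
  structure(list(name = as.character(name), bmdl10 = bmdl10,
                 concern_threshold = concern_threshold),
            class = "endpoint")
}

#' Packaged acrylamide endpoints
#'
#' Neurotoxicity (BMDL10 0.43 mg/kg bw/day, concern threshold 125) and two
#' carcinogenicity endpoints: Harderian gland tumours (0.17) and mammary gland
#' tumours (0.31), both with concern threshold 10,000.
#'
#' @return named list of [endpoint()] objects.
#' @export
default_endpoints <- function() {
  list(
    neurotoxic = endpoint("neurotoxic", 0.43, 125),
    carcinogenic_harderian = endpoint("carcinogenic_harderian", 0.17, 10000),
    carcinogenic_mammary = endpoint("carcinogenic_mammary", 0.31, 10000)
  )
}

#' Margin of Exposure distribution
#'
#' Transforms a simulated exposure distribution into the Margin of Exposure
#' MOE = BMDL10 / E, elementwise. The BMDL10 (mg/kg bw/day) is converted to
#' ng/kg bw/day internally, so MOE is dimensionless. Zero-exposure iterations
#' map to `Inf`; they can never count as below a finite concern threshold.
#'
#' @param exposure an [simulate_exposure()] result (E, ng/kg bw/day).
#' @param ep an [endpoint()].
#' @return object of class `moe_distribution`: list with `endpoint`,
#'   `age_group`, `values`, and `prob_below_threshold` (fraction of values
#'   strictly below the endpoint's concern threshold).
#' @examples
#' pool <- bootstrap_concentration(17, replicates = 1, noise_sd = 0)
#' ex <- simulate_exposure(pool, lognormal_from_moments(8, 0),
#'                         age_group("6 months", 8), simulation_config(10))
#' compute_moe(ex, endpoint("carc", 0.17, 10000))$values[1]  # 10000
#' @export
compute_moe <- function(exposure, ep) {
  stopifnot(inherits(exposure, "exposure_distribution"), inherits(ep, "endpoint"))
  E <- exposure$values
  if (all(E == 0)) warning("all exposures are zero: MOE distribution is degenerate (+Inf)")
  values <- (ep$bmdl10 * NG_PER_MG) / E
  values[E == 0] <- Inf
  out <- structure(
    list(endpoint = ep, age_group = exposure$age_group, values = values,
         prob_below_threshold = NA_real_),
    class = "moe_distribution"
  )
  out$prob_below_threshold <- prob_below(out, ep$concern_threshold)
  out
}

#' Probability of a MOE below a threshold
#'
#' Fraction of simulated MOE values strictly below the threshold (infinite
#' values, from zero-exposure iterations, never count). The strict-inequality
#' convention is fixed so reported probabilities are reproducible bit for bit;
#' with continuous simulated distributions the choice is immaterial.
#'
#' @param moe a [compute_moe()] distribution.
#' @param threshold concern threshold (dimensionless).
#' @return fraction in `[0, 1]`.
#' @examples
#' # two values straddling the threshold
#' @export
prob_below <- function(moe, threshold = moe$endpoint$concern_threshold) {
  stopifnot(inherits(moe, "moe_distribution"), length(moe$values) > 0)
  mean(is.finite(moe$values) & moe$values < threshold)
}

#' Empirical CDF of a MOE distribution on a grid
#'
#' Right-continuous empirical cumulative distribution function (the standard
#' `P(X <= t)` convention) evaluated at the supplied grid points. Evaluating
#' just below a threshold recovers [prob_below()] at that threshold.
#'
#' @param moe a [compute_moe()] distribution.
#' @param grid ascending numeric grid of MOE values.
#' @return data frame with columns `moe` (the grid) and `cumulative_fraction`.
#' @export
moe_ecdf <- function(moe, grid) {
  stopifnot(inherits(moe, "moe_distribution"), !is.unsorted(grid))
  F <- stats::ecdf(moe$values)
  data.frame(moe = grid, cumulative_fraction = F(grid))
}

#' @export
print.moe_distribution <- function(x, ...) {
  qs <- stats::quantile(x$values[is.finite(x$values)], c(0.05, 0.5, 0.95))
  cat(sprintf("MOE distribution [%s | %s, BMDL10 %.2f mg/kg bw/day]\n",
              x$age_group$label, x$endpoint$name, x$endpoint$bmdl10))
  cat(sprintf("  P(MOE < %s) = %.4f; P5 %.0f, median %.0f, P95 %.0f\n",
              format(x$endpoint$concern_threshold, big.mark = ","),
              x$prob_below_threshold, qs[1], qs[2], qs[3]))
  invisible(x)
}
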