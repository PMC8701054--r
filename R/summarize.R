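#' Censor-aware summary of a single category
#'
#' Computes n, mean, sample SD (n - 1 denominator), median, 95th percentile
#' (type-7 linear interpolation between closest ranks), minimum and maximum on
#' the policy-imputed values of one category, then applies the display rule
#' used by censor-aware survey tables: when the category contains censored
#' observations, a statistic whose imputed value falls below the LOD renders
#' as `<LOD`, and one falling below the LOQ renders as `<LOQ` (quantified-only
#' datasets always render numerically because quantified values are at or
#' above the LOQ by definition). Full precision is retained in the `values`
#' slot; only display rounds to integers.
#'
#' @param observations observations data frame (single category) with columns
#'   `category`, `value`, `status`.
#' @param policy a [censoring_policy()]; middle-bound by default.
#' @return a [category_summary()].
#' @examples
#' obs <- data.frame(sample_id = "s1", category = "Multigrain meal",
#'                   value = NA_real_, status = "below_lod")
#' summarize_category(obs[rep(1, 14), ])  # every column renders "<LOD"
#' @export
summarize_category <- function(observations, policy = censoring_policy()) {
  if (nrow(observations) == 0L) stop("observations must be non-empty")
  cats <- unique(as.character(observations$category))
  if (length(cats) != 1L) {
    stop("summarize_category expects a single category, got: ",
         paste(cats, collapse = ", "))
  }
  x <- impute(observations, policy)
  n <- length(x)
  vals <- c(
    mean = mean(x),
    sd = if (n > 1L) stats::sd(x) else 0,
    median = stats::median(x),
    p95 = unname(stats::quantile(x, 0.95, type = 7)),
    min = min(x),
    max = max(x)
  )
  any_censored <- any(observations$status != "quantified")
  flag_of <- function(v) {
    if (is.na(v) || !any_censored) return(NA_character_)
    if (v < policy$lod) "below_lod" else if (v < policy$loq) "below_loq" else NA_character_
  }
  flags <- vapply(vals, flag_of, character(1))
  flags[["sd"]] <- NA_character_  # SD shares the mean's cell in display
  out <- category_summary(
    category = cats, n = n,
    mean = vals[["mean"]], sd = vals[["sd"]], median = vals[["median"]],
    p95 = vals[["p95"]], min = vals[["min"]], max = vals[["max"]],
    lod = policy$lod, loq = policy$loq
  )
  # overwrite numeric parse with censor flags where the display rule applies,
  # but keep the numeric values available for round-trip checks
  out$flags[names(flags)] <- flags
  out$values[STAT_NAMES] <- vals[STAT_NAMES]
  out
}

#' Summarize a multi-category study
#'
#' Applies [summarize_category()] per category, preserving first-appearance
#' category order.
#'
#' @inheritParams summarize_category
#' @return list of [category_summary()] objects.
#' @export
summarize_study <- function(observations, policy = censoring_policy()) {
  cats <- unique(as.character(observations$category))
  out <- lapply(cats, function(cc) {
    summarize_category(observations[observations$category == cc, , drop = FALSE], policy)
  })
  names(out) <- cats
  out
}

#' Analytical limits from calibration-curve quality
#'
#' Computes the limit of detection as LOD = 3.3 sigma / S, with sigma the
#' standard deviation of the detector response and S the slope of the
#' calibration curve, and the limit of quantification as LOQ = 3 x LOD.
#'
#' @param response_sd standard deviation of the response (sigma), detector
#'   units.
#' @param slope calibration-curve slope (S), response units per ng/g.
#' @return named numeric vector `c(lod = , loq = )`, ng/g.
#' @examples
#' lod_loq_from_calibration(response_sd = 10, slope = 3.3)  # lod 10, loq 30
#' @export
lod_loq_from_calibration <- function(response_sd, slope) {
  stopifnot(is.numeric(response_sd), is.numeric(slope))
  if (slope <= 0) stop("calibration slope must be positive")
  if (response_sd < 0) stop("response SD must be nonnegative")
  lod <- 3.3 * response_sd / slope
  c(lod = lod, loq = 3 * lod)
}
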