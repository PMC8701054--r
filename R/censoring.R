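#' Censoring substitution policy
#'
#' Defines how left-censored concentration observations are replaced by
#' numeric values before any statistic is computed. The middle-bound rule
#' substitutes LOD/2 for values below the limit of detection (LOD) and LOQ/2
#' for values below the limit of quantification (LOQ); the lower-bound rule
#' substitutes 0 and LOD; the upper-bound rule substitutes LOD and LOQ.
#' Middle-bound is the default throughout the package; the other two exist
#' for sensitivity analysis.
#'
#' @param name one of `"middle_bound"` (default), `"lower_bound"`,
#'   `"upper_bound"`.
#' @param lod limit of detection, ng/g. Must be positive and below `loq`.
#' @param loq limit of quantification, ng/g.
#' @return an object of class `censoring_policy`.
#' @examples
#' pol <- censoring_policy("middle_bound", lod = 10, loq = 30)
#' pol$sub_lod  # 5
#' pol$sub_loq  # 15
#' @export
censoring_policy <- function(name = c("middle_bound", "lower_bound", "upper_bound"),
                             lod = 10, loq = 30) {
  name <- match.arg(name)
  stopifnot(is.numeric(lod), is.numeric(loq), length(lod) == 1L, length(loq) == 1L)
  if (!(lod > 0 && loq > 0)) stop("lod and loq must be positive")
  if (!(lod < loq)) stop("lod must be strictly below loq")
  subs <- switch(name,
    middle_bound = c(below_lod = lod / 2, below_loq = loq / 2),
    lower_bound  = c(below_lod = 0,       below_loq = lod),
    upper_bound  = c(below_lod = lod,     below_loq = loq)
  )
  structure(
    list(name = name, lod = lod, loq = loq,
         sub_lod = unname(subs["below_lod"]), sub_loq = unname(subs["below_loq"])),
    class = "censoring_policy"
  )
}

#' @export
print.censoring_policy <- function(x, ...) {
  cat(sprintf("Censoring policy: %s (LOD = %g, LOQ = %g ng/g)\n", x$name, x$lod, x$loq))
  cat(sprintf("  below LOD -> %g ng/g, below LOQ -> %g ng/g\n", x$sub_lod, x$sub_loq))
  invisible(x)
}

#' Substitute censored observations with numeric values
#'
#' Maps each observation to a concentration in ng/g under a
#' [censoring_policy()]. Quantified observations pass through unchanged;
#' censored observations receive the policy's substitution value. Order and
#' length are preserved, so the result aligns row-for-row with the input.
#'
#' @param observations a data frame of observations as produced by
#'   [reconstruct_category()] or [read_observations_csv()], with columns
#'   `value` (numeric, `NA` when censored) and `status` (one of
#'   `"quantified"`, `"below_loq"`, `"below_lod"`).
#' @param policy a [censoring_policy()].
#' @return numeric vector of imputed concentrations, ng/g.
#' @examples
#' obs <- data.frame(value = c(61, NA, NA),
#'                   status = c("quantified", "below_loq", "below_lod"))
#' impute(obs, censoring_policy("middle_bound"))  # 61 15 5
#' @export
impute <- function(observations, policy = censoring_policy()) {
  stopifnot(inherits(policy, "censoring_policy"))
  status <- as.character(observations$status)
  known <- c("quantified", "below_loq", "below_lod")
  bad <- setdiff(unique(status), known)
  if (length(bad)) {
    stop("unknown censor status token(s): ", paste(bad, collapse = ", "))
  }
  out <- observations$value
  out[status == "below_lod"] <- policy$sub_lod
  out[status == "below_loq"] <- policy$sub_loq
  if (anyNA(out)) stop("quantified observations must carry a numeric value")
  as.numeric(out)
}
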