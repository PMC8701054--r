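#' Bootstrap concentration distribution with measurement error
#'
#' Builds the simulated probability distribution of the food concentration C
#' by bootstrap resampling of the imputed empirical values: each replicate
#' draws `length(imputed_values)` observations with replacement, independent
#' zero-mean Gaussian noise of the given SD (representing assay uncertainty)
#' is added to every drawn value, negatives are clipped to zero (a
#' concentration is a physical quantity), and all replicates are pooled into
#' one vector. As the number of replicates grows, the pool mean converges to
#' the empirical mean and the pool variance to
#' `s^2 * (n - 1) / n + noise_sd^2` (population variance of the data plus the
#' noise variance), apart from the rare clipped draws.
#'
#' @param imputed_values numeric vector of concentrations, ng/g (already
#'   imputed; see [impute()]).
#' @param replicates bootstrap replicates (default 1000).
#' @param noise_sd SD of the additive Gaussian measurement error, ng/g
#'   (default 4; 0 gives a plain bootstrap).
#' @param seed integer seed; same seed gives a bit-identical pool.
#' @return object of class `concentration_pool`: list with `values`
#'   (length `source_n * replicates`), `source_n`, `replicates`, `noise_sd`,
#'   `seed`.
#' @examples
#' pool <- bootstrap_concentration(c(15, 40, 61, 109), replicates = 10, seed = 1)
#' length(pool$values)  # 40
#' @export
bootstrap_concentration <- function(imputed_values, replicates = 1000,
                                    noise_sd = 4, seed = 1L) {
  if (!length(imputed_values)) stop("imputed_values must be non-empty")
  stopifnot(is.numeric(imputed_values), all(is.finite(imputed_values)),
            all(imputed_values >= 0))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  n <- length(imputed_values)
  total <- n * replicates
  set.seed(as.integer(seed))
  draws <- imputed_values[sample.int(n, total, replace = TRUE)]
  if (noise_sd > 0) draws <- draws + stats::rnorm(total, 0, noise_sd)
  draws <- pmax(draws, 0)
  structure(
    list(values = draws, source_n = n, replicates = replicates,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "concentration_pool"
  )
}

#' @export
print.concentration_pool <- function(x, ...) {
  cat(sprintf("Concentration pool: %d values (%d empirical x %d replicates), noise SD %g ng/g\n",
              length(x$values), x$source_n, x$replicates, x$noise_sd))
  cat(sprintf("  mean %.2f, sd %.2f, range [%.2f, %.2f] ng/g\n",
              mean(x$values), stats::sd(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Export a concentration pool for audit
#'
#' @param pool a [bootstrap_concentration()] pool.
#' @param path CSV file path (single column `concentration_ng_g`).
#' @return `path`, invisibly.
#' @export
write_pool_csv <- function(pool, path) {
  stopifnot(inherits(pool, "concentration_pool"))
  utils::write.csv(data.frame(concentration_ng_g = pool$values), path,
                   row.names = FALSE)
  invisible(path)
}
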