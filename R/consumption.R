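#' Log-normal daily-consumption model from natural-scale moments
#'
#' Consumption surveys report the mean and SD of daily intake on the natural
#' scale (g/day); a log-normal consumption variable with those moments has
#' log-scale parameters obtained by moment matching:
#' sigma^2 = log(1 + (sd/mean)^2), mu = log(mean) - sigma^2 / 2. The resulting
#' distribution has exactly the requested natural-scale mean and SD, and every
#' draw from it is strictly positive.
#'
#' @param mean natural-scale mean daily consumption, g/day (> 0).
#' @param sd natural-scale SD of daily consumption, g/day (>= 0); `sd = 0`
#'   gives the degenerate point mass at `mean`.
#' @param label age-group label the model applies to.
#' @return object of class `consumption_model` with fields `label`, `mean`,
#'   `sd`, `mu`, `sigma`.
#' @examples
#' m <- lognormal_from_moments(10, 5)
#' m$sigma^2  # log(1.25)
#' exp(m$mu + m$sigma^2 / 2)  # 10
#' @export
lognormal_from_moments <- function(mean, sd, label = "") {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0) stop("consumption mean must be positive")
  if (!is.finite(sd) || sd < 0) stop("consumption sd must be nonnegative")
  sigma2 <- log1p((sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  structure(
    list(label = as.character(label), mean = mean, sd = sd,
         mu = mu, sigma = sqrt(sigma2)),
    class = "consumption_model"
  )
}

#' Log-normal consumption model from log-scale parameters
#'
#' Direct (mu, sigma) parameterization for workflows whose survey source
#' reports log-scale parameters; the implied natural-scale mean and SD are
#' filled in.
#'
#' @param mu,sigma log-scale location and spread.
#' @param label age-group label.
#' @return a `consumption_model`.
#' @export
lognormal_from_logscale <- function(mu, sigma, label = "") {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  m <- exp(mu + sigma^2 / 2)
  s <- m * sqrt(expm1(sigma^2))
  structure(
    list(label = as.character(label), mean = m, sd = s, mu = mu, sigma = sigma),
    class = "consumption_model"
  )
}

#' @export
print.consumption_model <- function(x, ...) {
  cat(sprintf("Log-normal consumption model%s: mean %.3g g/day, sd %.3g g/day (mu = %.4f, sigma = %.4f)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$mean, x$sd, x$mu, x$sigma))
  invisible(x)
}

#' Draw daily-consumption values
#'
#' @param model a [lognormal_from_moments()] model.
#' @param n_draws number of draws (>= 1).
#' @param seed integer seed; same seed reproduces the same draws.
#' @return numeric vector of `n_draws` strictly positive g/day values.
#' @examples
#' q <- generate_consumption(lognormal_from_moments(10, 5), 5, seed = 1)
#' @export
generate_consumption <- function(model, n_draws, seed = 1L) {
  stopifnot(inherits(model, "consumption_model"))
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop("n_draws must be >= 1")
  set.seed(as.integer(seed))
  stats::rlnorm(n_draws, meanlog = model$mu, sdlog = model$sigma)
}
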