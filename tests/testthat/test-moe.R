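moe_from_values <- function(E, ep = endpoint("carc", 0.17, 10000), bw = 8) {
  ex <- structure(list(age_group = age_group("test", bw), values = E,
                       config = simulation_config(length(E))),
                  class = "exposure_distribution")
  compute_moe(ex, ep)
}

test_that("the MOE ratio converts BMDL10 from mg to ng exactly", {
  md <- moe_from_values(17)
  expect_equal(md$values, 10000)          # 170,000 / 17
  md2 <- moe_from_values(0.17 * 1e6, endpoint("x", 0.17, 10000))
  expect_equal(md2$values, 1)             # E equal to the converted BMDL10
})

test_that("endpoints rescale the same exposure elementwise", {
  E <- c(5, 17, 120, 4000)
  m17 <- moe_from_values(E, endpoint("h", 0.17, 10000))
  m31 <- moe_from_values(E, endpoint("m", 0.31, 10000))
  m43 <- moe_from_values(E, endpoint("n", 0.43, 125))
  expect_equal(m31$values, m17$values * (0.31 / 0.17))
  expect_equal(m43$values, m17$values * (0.43 / 0.17))
  expect_lte(m31$prob_below_threshold, m17$prob_below_threshold)
})

test_that("prob_below counts strictly-below finite values only", {
  md <- moe_from_values(c(170000 / 5000, 170000 / 15000))  # MOE 5000, 15000
  expect_equal(prob_below(md, 10000), 0.5)
  expect_equal(prob_below(md, 4000), 0)
  boundary <- moe_from_values(17)  # MOE exactly 10,000
  expect_equal(prob_below(boundary, 10000), 0)  # strict inequality
})

test_that("zero exposures map to +Inf and never count as concern", {
  expect_warning(md <- moe_from_values(rep(0, 5)), "degenerate")
  expect_true(all(is.infinite(md$values)))
  expect_equal(prob_below(md, 10000), 0)
  mixed <- moe_from_values(c(0, 17))
  expect_equal(prob_below(mixed, 1e9), 0.5)  # the Inf is excluded
})

test_that("the empirical CDF matches the strict-below convention at thresholds", {
  exact <- endpoint("exact", 1, 10000)  # 1e6 ng, exactly representable
  md <- moe_from_values(1e6 / c(2000, 4000, 6000, 8000, 10000,
                                12000, 14000, 16000, 18000, 20000), exact)
  grid <- c(9999, 10000, 10001)
  cdf <- moe_ecdf(md, grid)
  expect_equal(cdf$cumulative_fraction, c(0.4, 0.5, 0.5))
  eps <- 10000 * .Machine$double.eps * 4
  just_below <- moe_ecdf(md, 10000 - eps)$cumulative_fraction
  expect_equal(just_below, prob_below(md, 10000))
  one <- moe_from_values(100, exact)  # single value exactly 10,000
  expect_equal(moe_ecdf(one, c(9999, 10000, 10001))$cumulative_fraction, c(0, 1, 1))
})

test_that("prob_below is nonincreasing in body weight under common random numbers", {
  x <- impute(reconstruct_category(biscuit_row(), seed = 1)$observations)
  pool <- bootstrap_concentration(x, replicates = 500, noise_sd = 4, seed = 2)
  cm <- lognormal_from_moments(20, 15)
  cfg <- simulation_config(iterations = 5000, master_seed = 13)
  probs <- vapply(c(8.0, 9.4, 10.9), function(bw) {
    ex <- simulate_exposure(pool, cm, age_group(sprintf("%g kg", bw), bw), cfg)
    compute_moe(ex, endpoint("carc", 0.17, 10000))$prob_below_threshold
  }, numeric(1))
  expect_true(all(diff(probs) <= 0))
})

test_that("endpoint construction validates its parameters", {
  expect_error(endpoint("x", 0, 125), "bmdl10")
  expect_error(endpoint("x", 0.17, -1), "threshold")
  eps <- default_endpoints()
  expect_equal(vapply(eps, `[[`, numeric(1), "bmdl10"),
               c(neurotoxic = 0.43, carcinogenic_harderian = 0.17,
                 carcinogenic_mammary = 0.31))
})
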