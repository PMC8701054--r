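test_that("fully below-LOD categories render every column as <LOD", {
  obs <- make_observations(rep(NA_real_, 14), rep("below_lod", 14), "Multigrain meal")
  s <- summarize_category(obs, mid_policy())
  expect_true(all(s$flags[c("mean", "median", "p95", "min", "max")] == "below_lod"))
  expect_equal(s$values[["mean"]], 5)  # LOD/2 underneath the token
})

test_that("display flags follow the imputed value against LOD and LOQ", {
  # sweet-snack-like mix: 2 below LOD + 10 below LOQ
  obs <- make_observations(rep(NA_real_, 12),
                           c(rep("below_lod", 2), rep("below_loq", 10)))
  s <- summarize_category(obs, mid_policy())
  expect_identical(s$flags[["mean"]], "below_loq")   # 13.33 < LOQ
  expect_identical(s$flags[["min"]], "below_lod")    # 5 < LOD
  expect_identical(s$flags[["max"]], "below_loq")
  # plum-like mix keeps the numeric tail numeric
  obs2 <- make_observations(c(rep(NA_real_, 10), 32, 32),
                            c(rep("below_lod", 2), rep("below_loq", 8),
                              "quantified", "quantified"))
  s2 <- summarize_category(obs2, mid_policy())
  expect_identical(s2$flags[["mean"]], "below_loq")
  expect_true(is.na(s2$flags[["p95"]]))
  expect_equal(s2$values[["p95"]], 32)
  expect_equal(s2$values[["max"]], 32)
})

test_that("a single quantified observation summarizes to itself with zero SD", {
  obs <- make_observations(47.5, "quantified")
  s <- summarize_category(obs, mid_policy())
  expect_equal(unname(s$values[c("mean", "median", "p95", "min", "max")]), rep(47.5, 5))
  expect_equal(s$values[["sd"]], 0)
  expect_true(all(is.na(s$flags)))  # no censoring, everything numeric
})

test_that("summarize_category uses the sample SD and the type-7 95th percentile", {
  vals <- c(31, 40, 52, 66, 80, 95)
  obs <- make_observations(vals, rep("quantified", 6))
  s <- summarize_category(obs, mid_policy())
  expect_equal(s$values[["sd"]], sd(vals))
  expect_equal(s$values[["p95"]], unname(quantile(vals, 0.95, type = 7)))
  expect_equal(s$values[["median"]], median(vals))
})

test_that("mixed-category input is rejected", {
  obs <- rbind(make_observations(45, "quantified", "A"),
               make_observations(50, "quantified", "B"))
  expect_error(summarize_category(obs, mid_policy()), "single category")
})
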