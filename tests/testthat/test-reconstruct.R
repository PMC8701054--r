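test_that("the whole-biscuit row reconstructs to its printed statistics", {
  rec <- reconstruct_category(biscuit_row(), seed = 1)
  x <- impute(rec$observations, mid_policy())
  expect_length(x, 20)
  expect_equal(mean(x), 61, tolerance = 0.5 / 61)
  expect_equal(sd(x), 20, tolerance = 1 / 20)
  expect_equal(median(x), 61, tolerance = 0.5 / 61)
  expect_equal(unname(quantile(x, 0.95, type = 7)), 79, tolerance = 1 / 79)
  expect_equal(max(x), 109)
  expect_equal(min(x), 15)  # the LOQ/2 substitution of the censored minimum
  st <- rec$observations$status
  expect_equal(sum(st == "below_loq"), 1)
  expect_equal(sum(st == "below_lod"), 0)
  expect_true(all(rec$observations$value[st == "quantified"] >= 30))
})

test_that("fully censored rows reconstruct to pure below-LOD datasets", {
  multigrain <- table1_summaries()[[3]]
  rec <- reconstruct_category(multigrain, seed = 5)
  expect_equal(nrow(rec$observations), 14)
  expect_true(all(rec$observations$status == "below_lod"))
  expect_true(all(is.na(rec$observations$value)))
  expect_equal(rec$max_constraint_residual, 0)
})

test_that("a degenerate single-point row reconstructs to that point", {
  s <- category_summary("One", 1, 83, NA, 83, 83, 83, 83)
  rec <- reconstruct_category(s, seed = 2)
  expect_equal(nrow(rec$observations), 1)
  expect_identical(rec$observations$status, "quantified")
  expect_equal(rec$observations$value, 83)
})

test_that("reconstruction is deterministic in the seed yet seed-dependent in the data", {
  a <- reconstruct_category(biscuit_row(), seed = 10)
  b <- reconstruct_category(biscuit_row(), seed = 10)
  expect_identical(a$observations, b$observations)
  c <- reconstruct_category(biscuit_row(), seed = 11)
  # different feasible dataset, same achieved summary within tolerance
  expect_false(identical(a$observations$value, c$observations$value))
  expect_equal(mean(impute(c$observations)), mean(impute(a$observations)),
               tolerance = 1 / 61)
})

test_that("an inconsistent printed P95 is dropped with a warning (or raised on request)", {
  expect_warning(rec <- reconstruct_category(ground_row(), seed = 1),
                 "P95")
  expect_identical(rec$dropped_constraints, "p95")
  x <- impute(rec$observations, mid_policy())
  expect_equal(mean(x), 39, tolerance = 0.5 / 39)
  expect_equal(median(x), 36, tolerance = 0.5 / 36)
  expect_equal(max(x), 55)
  expect_error(reconstruct_category(ground_row(), seed = 1, p95_action = "error"),
               class = "dietmoe_infeasible")
})

test_that("genuinely infeasible constraint sets fail with the violated constraint named", {
  bad <- category_summary("Bad", 10, 50, 5, 70, NA, 30, 60)  # median > max
  expect_error(reconstruct_category(bad, seed = 1), "median")
  bad2 <- category_summary("Bad2", 10, 50, 5, 20, 55, 15, 60)  # numeric min below LOQ
  expect_error(reconstruct_category(bad2, seed = 1), "LOQ")
})

test_that("summarize–reconstruct round trip holds on generated feasible summaries", {
  for (case in list(list(seed = 101, censored = FALSE),
                    list(seed = 202, censored = TRUE),
                    list(seed = 303, censored = FALSE),
                    list(seed = 404, censored = TRUE))) {
    s <- random_feasible_summary(case$seed, n = 16, censored = case$censored)
    rec <- reconstruct_category(s, seed = case$seed + 1)
    got <- summarize_category(rec$observations, mid_policy())
    tol <- c(mean = 0.5, sd = 1.0, median = 0.5, p95 = 1.0, min = 0.5, max = 0.5)
    for (stat in names(tol)) {
      if (is.na(s$values[[stat]])) next
      expect_lt(abs(got$values[[stat]] - s$values[[stat]]), tol[[stat]] + 1e-8)
    }
    expect_identical(got$flags, s$flags)
  }
})

test_that("the six-category study assembles 90 observations with 80% detectable", {
  study <- suppressWarnings(generate_study(table1_summaries(), seed = 1))
  expect_equal(nrow(study), 90)
  counts <- table(study$category)[c("Biscuits", "Ground biscuits",
                                    "Multigrain meal", "Sweet snacks",
                                    "Savory snacks", "Plum puree")]
  expect_equal(as.integer(counts), c(20L, 20L, 14L, 12L, 12L, 12L))
  expect_equal(detectable_fraction(study), 0.8)
  again <- suppressWarnings(generate_study(table1_summaries(), seed = 1))
  expect_identical(study$value, again$value)
  expect_identical(study$status, again$status)
})
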