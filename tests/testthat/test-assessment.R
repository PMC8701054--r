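example_config <- function(iterations = 2000) {
  cfg <- read_run_config(system.file("extdata", "example_config.json",
                                     package = "dietmoe"))
  cfg$simulation$iterations <- as.integer(iterations)
  cfg
}

test_that("the packaged configuration yields one summary per age group and endpoint", {
  a <- suppressWarnings(run_assessment(example_config()))
  expect_s3_class(a, "moe_assessment")
  expect_equal(nrow(a$report), 9)  # 3 age groups x 3 endpoints
  expect_setequal(unique(a$report$age_group), c("6 months", "12 months", "18 months"))
  expect_setequal(unique(a$report$endpoint),
                  c("neurotoxic", "carcinogenic_harderian", "carcinogenic_mammary"))
  expect_true(all(a$report$prob_below >= 0 & a$report$prob_below <= 1))
  expect_true(all(a$report$moe_p5 <= a$report$moe_p50))
  expect_true(all(a$report$moe_p50 <= a$report$moe_p95))
})

test_that("repeated runs with one master seed write byte-identical reports", {
  cfg <- example_config()
  a <- suppressWarnings(run_assessment(cfg, seed = 303))
  b <- suppressWarnings(run_assessment(cfg, seed = 303))
  expect_identical(a$report, b$report)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(a, d1)
  write_report(b, d2)
  for (f in c("report.json", "moe_summary.csv", "exposure.csv", "observations.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a degenerate configuration reproduces the hand-computed MOE chain", {
  # C = 61 ng/g, Q = 10 g/day, BW = 8.0 kg, BMDL10 = 0.43 -> MOE = 430000/76.25
  cfg <- run_config(
    summaries = list(category_summary("Only", 1, 61, NA, 61, 61, 61, 61)),
    pool_categories = "Only",
    age_groups = list(`6 months` = age_group("6 months", 8.0)),
    endpoints = list(neurotoxic = endpoint("neurotoxic", 0.43, 125)),
    consumption = list(`6 months` = lognormal_from_moments(10, 0)),
    simulation = simulation_config(iterations = 500, bootstrap_replicates = 10,
                                   noise_sd = 0, master_seed = 1)
  )
  a <- run_assessment(cfg)
  expected <- 430000 / 76.25  # ~5639.344
  expect_equal(unname(unlist(a$report[, c("moe_p5", "moe_p25", "moe_p50",
                                          "moe_p75", "moe_p95")])),
               rep(expected, 5))
  expect_equal(a$report$prob_below, 0)
})

test_that("configuration validation catches missing consumption models", {
  expect_error(
    run_config(age_groups = default_age_groups(),
               consumption = list(`6 months` = lognormal_from_moments(10, 5))),
    "12 months"
  )
})

test_that("the JSON config round-trips its simulation settings", {
  cfg <- read_run_config(system.file("extdata", "example_config.json",
                                     package = "dietmoe"))
  expect_equal(cfg$simulation$iterations, 10000L)
  expect_equal(cfg$simulation$bootstrap_replicates, 1000L)
  expect_equal(cfg$simulation$noise_sd, 4)
  expect_equal(cfg$simulation$censoring_policy, "middle_bound")
  expect_equal(cfg$consumption[["6 months"]]$mean, 15)
  expect_s3_class(cfg$consumption[["6 months"]], "consumption_model")
})
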