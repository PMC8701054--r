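table1_summaries <- function() read_summary_csv(table1_path())

biscuit_row <- function() table1_summaries()[[1]]
ground_row <- function() table1_summaries()[[2]]

mid_policy <- function() censoring_policy("middle_bound", lod = 10, loq = 30)

make_observations <- function(values, statuses, category = "Test") {
  data.frame(
    sample_id = sprintf("%s_%02d", category, seq_along(statuses)),
    category = category,
    value = ifelse(statuses == "quantified", values, NA_real_),
    status = statuses,
    stringsAsFactors = FALSE
  )
}

# a fully specified feasible summary built from a known witness dataset
random_feasible_summary <- function(seed, n = 16, censored = FALSE) {
  set.seed(seed)
  m <- if (censored) n - 1L else n
  vals <- sort(round(runif(m, 35, 180), 2))
  statuses <- c(rep("below_loq", n - m), rep("quantified", m))
  obs <- make_observations(c(rep(NA_real_, n - m), vals), statuses)
  summarize_category(obs, mid_policy())
}

degenerate_pool <- function(value) {
  bootstrap_concentration(value, replicates = 1, noise_sd = 0, seed = 1)
}
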