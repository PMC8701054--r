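STAT_NAMES <- c("mean", "sd", "median", "p95", "min", "max")
CENSOR_TOKENS <- c(below_lod = "<LOD", below_loq = "<LOQ")

parse_stat <- function(x, what) {
  if (length(x) != 1L) stop("statistic '", what, "' must have length 1")
  if (is.numeric(x)) {
    if (is.na(x)) return(list(value = NA_real_, flag = NA_character_))
    if (x < 0) stop("statistic '", what, "' must be nonnegative")
    return(list(value = as.numeric(x), flag = NA_character_))
  }
  x <- trimws(as.character(x))
  if (x == "" || is.na(x)) return(list(value = NA_real_, flag = NA_character_))
  if (toupper(x) == "<LOD") return(list(value = NA_real_, flag = "below_lod"))
  if (toupper(x) == "<LOQ") return(list(value = NA_real_, flag = "below_loq"))
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("cannot parse statistic '", what, "': ", x)
  if (v < 0) stop("statistic '", what, "' must be nonnegative")
  list(value = v, flag = NA_character_)
}

#' One censor-aware concentration summary row
#'
#' Represents a per-category summary of concentration measurements the way
#' surveillance studies print them: n, mean, SD, median, 95th percentile,
#' minimum and maximum, where any statistic may be replaced by a censor token
#' (`"<LOD"` or `"<LOQ"`) when the underlying value sits below the analytical
#' limits. A summary row is both the output of [summarize_category()] and the
#' constraint set that [reconstruct_category()] inverts.
#'
#' Each statistic may be given as a number (ng/g) or as the literal token
#' `"<LOD"` / `"<LOQ"`. The constructor is permissive about order violations
#' among the printed statistics (published tables occasionally contain them);
#' [validate_summary()] reports any violations, and the reconstruction layer
#' decides how to treat them.
#'
#' @param category category label, e.g. `"Biscuits"`.
#' @param n number of samples in the category.
#' @param mean,sd,median,p95,min,max summary statistics, numeric ng/g or a
#'   censor token. `sd` may be `NA` (e.g. n = 1 or fully censored rows).
#' @param lod,loq analytical limits of detection / quantification, ng/g.
#' @return object of class `category_summary` with elements `category`, `n`,
#'   `values` (named numeric, `NA` where censored), `flags` (named character,
#'   `NA` where numeric), `lod`, `loq`.
#' @examples
#' category_summary("Biscuits", 20, mean = 61, sd = 20, median = 61,
#'                  p95 = 79, min = "<LOQ", max = 109)
#' @export
category_summary <- function(category, n, mean, sd = NA, median, p95, min, max,
                             lod = 10, loq = 30) {
  stopifnot(length(category) == 1L, !is.na(category))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!(lod > 0 && loq > 0 && lod < loq)) stop("need 0 < lod < loq")
  stats <- list(mean = mean, sd = sd, median = median, p95 = p95, min = min, max = max)
  parsed <- mapply(parse_stat, stats, names(stats), SIMPLIFY = FALSE)
  values <- vapply(parsed, `[[`, numeric(1), "value")
  flags <- vapply(parsed, `[[`, character(1), "flag")
  structure(
    list(category = as.character(category), n = n,
         values = values, flags = flags, lod = lod, loq = loq),
    class = "category_summary"
  )
}

#' Check a summary row's internal consistency
#'
#' Returns a character vector naming every violated ordering constraint among
#' the numeric statistics of a [category_summary()] (empty when consistent):
#' min <= median <= p95 <= max and min <= mean <= max.
#'
#' @param summary a [category_summary()].
#' @return character vector of violation descriptions (length 0 if none).
#' @export
validate_summary <- function(summary) {
  stopifnot(inherits(summary, "category_summary"))
  v <- summary$values
  bad <- character(0)
  chk <- function(a, b) {
    if (!is.na(v[a]) && !is.na(v[b]) && v[a] > v[b]) {
      sprintf("%s (%g) > %s (%g)", a, v[a], b, v[b])
    } else character(0)
  }
  bad <- c(bad, chk("min", "median"), chk("median", "p95"), chk("p95", "max"),
           chk("median", "max"), chk("min", "max"),
           chk("min", "mean"), chk("mean", "max"))
  bad
}

format_stat_cell <- function(summary, what, digits = 0) {
  f <- summary$flags[[what]]
  if (!is.na(f)) return(CENSOR_TOKENS[[f]])
  v <- summary$values[[what]]
  if (is.na(v)) return("")
  format(round(v, digits))
}

#' @export
print.category_summary <- function(x, ...) {
  mean_cell <- if (!is.na(x$flags[["mean"]])) {
    CENSOR_TOKENS[[x$flags[["mean"]]]]
  } else if (!is.na(x$values[["sd"]])) {
    sprintf("%s ± %s", format_stat_cell(x, "mean"), format_stat_cell(x, "sd"))
  } else {
    format_stat_cell(x, "mean")
  }
  cat(sprintf("%s (n = %d): mean %s, median %s, P95 %s, min %s, max %s [ng/g]\n",
              x$category, x$n, mean_cell,
              format_stat_cell(x, "median"), format_stat_cell(x, "p95"),
              format_stat_cell(x, "min"), format_stat_cell(x, "max")))
  invisible(x)
}

#' Read censor-aware summary rows from CSV
#'
#' Expects columns `category, n, mean, sd, median, p95, min, max`; censored
#' cells hold the literal tokens `<LOD` or `<LOQ` and `sd` may be empty. The
#' packaged acrylamide baby-food survey table ships in this format, see
#' [table1_path()].
#'
#' @param path CSV file path.
#' @param lod,loq analytical limits applying to all rows, ng/g.
#' @return list of [category_summary()] objects.
#' @examples
#' summaries <- read_summary_csv(table1_path())
#' summaries[[1]]
#' @export
read_summary_csv <- function(path, lod = 10, loq = 30) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  need <- c("category", "n", STAT_NAMES)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("summary CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    category_summary(row$category, as.integer(row$n), row$mean, row$sd,
                     row$median, row$p95, row$min, row$max, lod = lod, loq = loq)
  })
}

#' Path to the packaged six-category summary table
#'
#' Location of the CSV fixture holding the published Table-1-style summary of
#' acrylamide in 90 baby-food samples over six categories (whole biscuits,
#' ground biscuits, multigrain meal, sweet snacks, savory snacks, plum
#' puree), with LOD = 10 ng/g and LOQ = 30 ng/g.
#'
#' @return file path of the CSV.
#' @export
table1_path <- function() {
  system.file("extdata", "table1_acrylamide.csv", package = "dietmoe", mustWork = TRUE)
}

#' Write / read per-sample observations as CSV
#'
#' Observations are stored with columns `sample_id, category, value, status`;
#' `value` is empty when the observation is censored.
#'
#' @param observations observations data frame.
#' @param path CSV file path.
#' @return `write_observations_csv` returns `path` invisibly;
#'   `read_observations_csv` returns the observations data frame.
#' @export
write_observations_csv <- function(observations, path) {
  df <- observations[, c("sample_id", "category", "value", "status")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- suppressWarnings(as.numeric(df$value))
  df
}
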