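#' Worked-example chart-review counts
#'
#' Per-bin chart-review outcomes for 120 controls sampled across the ten
#' coarse risk bins of a dementia risk-score validation (30 reviews in the
#' lowest bin, 10 in each other bin): counts of reviews concluding
#' Dementia, Unclear, and Non-Dementia. Used by the package's worked example
#' and by the calibration tests; feed it to [compute_rates()] and
#' [fit_rate_line()] to reproduce the rate table and line fits.
#'
#' @return A tibble: `bin`, `bin_lo`, `bin_hi`, `n_dementia`, `n_unclear`,
#'   `n_non`.
#' @export
#' @examples
#' counts <- example_review_counts()
#' rates <- compute_rates(counts)
example_review_counts <- function() {
  path <- system.file("extdata", "example_review_counts.csv",
                      package = "silverphen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
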