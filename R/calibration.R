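#' Stratified chart-review sampling design
#'
#' The default design reviews 10 controls from each of the 10 coarse risk
#' bins plus an extra 20 from the lowest bin (which typically holds several
#' times more controls than the rest), 120 reviews in total.
#'
#' @param per_bin Controls sampled per coarse bin.
#' @param extra_low_bin Additional controls sampled from bin 1.
#' @return A `review_design` list with `per_bin`, `extra_low_bin`, `total`.
#' @export
review_design <- function(per_bin = 10, extra_low_bin = 20) {
  per_bin <- check_count(per_bin, "per_bin")
  extra_low_bin <- check_count(extra_low_bin, "extra_low_bin", min = 0)
  structure(list(per_bin = per_bin, extra_low_bin = extra_low_bin,
                 total = 10L * per_bin + extra_low_bin),
            class = "review_design")
}

#' Draw the stratified review sample
#'
#' Samples uniformly without replacement within each coarse bin. A bin with
#' fewer controls than its quota contributes all of them, with a warning
#' about the shortfall.
#'
#' @param scores Score tibble for controls (`subject_id`, `score`,
#'   `coarse_bin`).
#' @param design A [review_design()].
#' @param seed Integer seed.
#' @return The sampled rows of `scores`.
#' @export
draw_review_sample <- function(scores, design = review_design(), seed = 1) {
  stopifnot(inherits(design, "review_design"))
  quota <- rep(design$per_bin, 10)
  quota[1] <- quota[1] + design$extra_low_bin
  withr::with_seed(seed, {
    out <- lapply(1:10, function(b) {
      rows <- scores[scores$coarse_bin == b, , drop = FALSE]
      if (nrow(rows) < quota[b]) {
        warning(sprintf("coarse bin %d holds %d control(s), quota %d: taking all",
                        b, nrow(rows), quota[b]), call. = FALSE)
        return(rows)
      }
      rows[sample.int(nrow(rows), quota[b]), , drop = FALSE]
    })
    dplyr::bind_rows(out)
  })
}

#' Per-bin review counts
#'
#' Tallies review labels by coarse risk bin.
#'
#' @param reviewed Tibble with `coarse_bin` and `review_label` in
#'   `{"Dementia", "Unclear", "Non-Dementia"}`.
#' @return A tibble per bin: `bin`, `bin_lo`, `bin_hi`, `n_dementia`,
#'   `n_unclear`, `n_non`.
#' @export
tally_review <- function(reviewed) {
  stopifnot(all(reviewed$review_label %in%
                  c("Dementia", "Unclear", "Non-Dementia")))
  tibble::tibble(bin = 1:10) |>
    dplyr::mutate(
      bin_lo = (.data$bin - 1) / 10, bin_hi = .data$bin / 10,
      n_dementia = vapply(.data$bin, function(b)
        sum(reviewed$coarse_bin == b & reviewed$review_label == "Dementia"),
        integer(1)),
      n_unclear = vapply(.data$bin, function(b)
        sum(reviewed$coarse_bin == b & reviewed$review_label == "Unclear"),
        integer(1)),
      n_non = vapply(.data$bin, function(b)
        sum(reviewed$coarse_bin == b &
              reviewed$review_label == "Non-Dementia"), integer(1))
    )
}

#' Undiagnosed-dementia rate per bin under both Unclear policies
#'
#' Review charts that lack enough information to call are labelled
#' `"Unclear"`; all calibration quantities are computed under both ways of
#' resolving them. With per-bin counts d (dementia), u (unclear) and
#' n (non-dementia):
#' * `unclear_dementia`: rate = (d + u) / (d + u + n)
#' * `unclear_nondementia`: rate = d / (d + u + n)
#'
#' Rates are carried at full precision; rounding is for display only. Bins
#' with no reviewed subjects have an undefined rate (`NA`) and are excluded
#' from line fitting with a warning there.
#'
#' @param counts Count tibble from [tally_review()] (or with the same
#'   columns).
#' @return A long tibble: `bin`, `midpoint`, `policy`, `n_reviewed`, `rate`.
#' @export
compute_rates <- function(counts) {
  stopifnot(all(c("bin_lo", "bin_hi", "n_dementia", "n_unclear", "n_non")
                %in% names(counts)))
  total <- counts$n_dementia + counts$n_unclear + counts$n_non
  base <- tibble::tibble(
    bin = counts$bin,
    midpoint = (counts$bin_lo + counts$bin_hi) / 2,
    n_reviewed = total
  )
  dplyr::bind_rows(
    dplyr::mutate(base, policy = "unclear_dementia",
                  rate = (counts$n_dementia + counts$n_unclear) /
                    ifelse(total == 0, NA_real_, total)),
    dplyr::mutate(base, policy = "unclear_nondementia",
                  rate = counts$n_dementia /
                    ifelse(total == 0, NA_real_, total))
  ) |>
    dplyr::relocate("policy", .after = "midpoint")
}

#' Fit the undiagnosed-rate line
#'
#' Fits ordinary least squares of per-bin undiagnosed rates on bin midpoints,
#' both with a free intercept (`y = b0 + b1 x`) and through the origin
#' (`y = b x`, for which the slope has the closed form
#' `sum(x*y) / sum(x^2)`). The free-intercept fit provides the t-test of
#' `b0 = 0` (df = n - 2): when the intercept is not significantly different
#' from zero at `alpha`, the zero-intercept slope is the one carried into
#' downstream undiagnosed-count estimation; both fits are always reported.
#'
#' @param rates Numeric vector of per-bin rates (NAs dropped with a warning).
#' @param midpoints Numeric vector of bin midpoints, same length.
#' @param alpha Significance level of the intercept test (default 0.05).
#' @return A `rate_line_fit` object with components `intercept`, `slope`
#'   (free-intercept fit, with `se`, `t`, `p_value` each of length 2 for
#'   (intercept, slope)), `slope_zero` (+ `se_zero`, `p_zero`),
#'   `use_zero_intercept`, `n`.
#' @export
fit_rate_line <- function(rates, midpoints, alpha = 0.05) {
  stopifnot(length(rates) == length(midpoints))
  ok <- !is.na(rates) & !is.na(midpoints)
  if (any(!ok)) {
    warning(sprintf("dropping %d bin(s) with undefined rate", sum(!ok)),
            call. = FALSE)
  }
  y <- rates[ok]; x <- midpoints[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 rate points to fit the line",
                  call. = FALSE)

  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients  # estimate, se, t, p (df = n - 2)

  b_zero <- sum(x * y) / sum(x^2)
  rss0 <- sum((y - b_zero * x)^2)
  se_zero <- sqrt(rss0 / (n - 1) / sum(x^2))
  p_zero <- 2 * pt(abs(b_zero / se_zero), df = n - 1, lower.tail = FALSE)

  structure(
    list(intercept = sm[1, 1], slope = sm[2, 1],
         se = sm[, 2], t = sm[, 3], p_value = sm[, 4],
         slope_zero = b_zero, se_zero = se_zero, p_zero = p_zero,
         use_zero_intercept = sm[1, 4] > alpha, alpha = alpha,
         n = n, x = x, y = y),
    class = "rate_line_fit"
  )
}

#' @export
print.rate_line_fit <- function(x, ...) {
  cat(sprintf(
    "<rate_line_fit> y = %.4f + %.4f x  (p[b0] = %.3f%s); zero-intercept slope %.4f\n",
    x$intercept, x$slope, x$p_value[1],
    if (x$use_zero_intercept) ", not significant: zero-intercept line adopted"
    else "", x$slope_zero))
  invisible(x)
}

#' @rdname fit_rate_line
#' @param x A `rate_line_fit`.
#' @param ... Unused.
#' @export
tidy.rate_line_fit <- function(x, ...) {
  tibble::tibble(
    model = c("intercept", "intercept", "zero_intercept"),
    term = c("(Intercept)", "slope", "slope"),
    estimate = c(x$intercept, x$slope, x$slope_zero),
    std.error = c(unname(x$se), x$se_zero),
    p.value = c(unname(x$p_value), x$p_zero)
  )
}

#' @rdname fit_rate_line
#' @export
glance.rate_line_fit <- function(x, ...) {
  tibble::tibble(n = x$n, intercept_p = unname(x$p_value[1]),
                 use_zero_intercept = x$use_zero_intercept,
                 slope_zero = x$slope_zero)
}

#' Cohen's kappa with an asymptotic confidence interval
#'
#' Chance-corrected agreement between two raters,
#' `kappa = (p_o - p_e) / (1 - p_e)`, with a Wald-style interval from the
#' large-sample standard error, truncated to `[-1, 1]`. When both raters are
#' constant and identical, chance agreement is 1 and kappa is taken as 1 by
#' convention, flagged in `degenerate`.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `kappa`, `se`, `conf_low`, `conf_high`, `p_observed`,
#'   `p_expected`, `n`, `degenerate`.
#' @export
cohen_kappa <- function(labels_a, labels_b, conf_level = 0.95) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    return(tibble::tibble(kappa = 1, se = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, p_observed = p_o,
                          p_expected = p_e, n = n, degenerate = TRUE))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(kappa = kappa, se = se,
                 conf_low = max(-1, kappa - zq * se),
                 conf_high = min(1, kappa + zq * se),
                 p_observed = p_o, p_expected = p_e, n = n,
                 degenerate = FALSE)
}
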