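#' Aggregate structured events to binary subject features
#'
#' Each (domain, code) pair becomes a candidate feature; a subject scores 1
#' when they have at least one in-window event with that code (presence, not
#' count). Events outside the subject's observation window
#' `[index_date - window_days, index_date)` are rejected and their count
#' reported.
#'
#' @param events Event tibble (`subject_id`, `event_date`, `domain`, `code`).
#' @param cohort Cohort tibble (`subject_id`, `index_date`); fixes the output
#'   subjects and their order.
#' @param window_days Observation window length in days.
#' @return A tibble: `subject_id` plus one 0/1 integer column per feature,
#'   named `<domain>_<code>` in lower case (e.g. `icd_780.93`).
#' @export
aggregate_structured <- function(events, cohort, window_days = 1095) {
  idx <- cohort$index_date[match(events$subject_id, cohort$subject_id)]
  if (anyNA(idx)) stop("events reference subjects absent from the cohort",
                       call. = FALSE)
  in_window <- events$event_date >= (idx - window_days) &
               events$event_date < idx
  if (any(!in_window)) {
    message(sprintf("rejected %d event(s) outside the observation window",
                    sum(!in_window)))
    events <- events[in_window, , drop = FALSE]
  }
  feats <- events |>
    dplyr::mutate(feature = paste0(tolower(.data$domain), "_", .data$code)) |>
    dplyr::distinct(.data$subject_id, .data$feature) |>
    dplyr::mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "feature", values_from = "present",
                       values_fill = 0L)
  feats <- feats[, c("subject_id", sort(setdiff(names(feats), "subject_id")))]
  out <- dplyr::left_join(dplyr::select(cohort, "subject_id"), feats,
                          by = "subject_id")
  out[is.na(out)] <- 0L
  out
}

#' Combine structured and topic features into one feature matrix
#'
#' @param structured Tibble from [aggregate_structured()].
#' @param topics Tibble from [subject_topic_presence()] (may be `NULL`).
#' @return A tibble with `subject_id` and one 0/1 column per feature.
#' @export
build_feature_matrix <- function(structured, topics = NULL) {
  if (is.null(topics)) return(structured)
  dplyr::inner_join(structured, topics, by = "subject_id")
}

#' Per-feature association statistics against case/control status
#'
#' For every binary feature: prevalence among cases and controls, the phi
#' coefficient (the Pearson correlation of the two binary indicators), and
#' the odds ratio from the 2x2 table. When any cell of the table is zero the
#' Haldane–Anscombe correction (0.5 added to every cell) keeps the odds
#' ratio finite; non-degenerate tables are left uncorrected. A feature that
#' is constant across subjects has undefined correlation and gets `phi = 0`
#' by convention, flagged in the `constant` column.
#'
#' @param features Feature tibble (`subject_id` + 0/1 columns).
#' @param cohort Cohort tibble with `subject_id` and `group`.
#' @return A tibble: `feature`, `prev_case`, `prev_ctrl`, `phi`,
#'   `odds_ratio`, `constant`.
#' @export
compute_feature_stats <- function(features, cohort) {
  y <- cohort$group[match(features$subject_id, cohort$subject_id)] == "case"
  if (anyNA(y)) stop("features reference subjects absent from the cohort",
                     call. = FALSE)
  X <- as.matrix(features[, setdiff(names(features), "subject_id")])
  n1 <- sum(y); n0 <- sum(!y)
  a <- colSums(X[y, , drop = FALSE])        # case & feature present
  c_ <- colSums(X[!y, , drop = FALSE])      # control & feature present
  b <- n1 - a
  d <- n0 - c_

  phi <- (a * d - b * c_) /
    sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
  constant <- (a + c_) == 0 | (b + d) == 0
  phi[constant] <- 0

  zero_cell <- a == 0 | b == 0 | c_ == 0 | d == 0
  a2 <- a + 0.5 * zero_cell; b2 <- b + 0.5 * zero_cell
  c2 <- c_ + 0.5 * zero_cell; d2 <- d + 0.5 * zero_cell
  or <- (a2 * d2) / (b2 * c2)

  tibble::tibble(feature = colnames(X),
                 prev_case = as.numeric(a / n1),
                 prev_ctrl = as.numeric(c_ / n0),
                 phi = as.numeric(phi), odds_ratio = as.numeric(or),
                 constant = unname(constant))
}

#' Feature selection rule
#'
#' Keeps features present in more than `min_prevalence` of cases or of
#' controls that are additionally either correlated with case status
#' (`|phi| > phi_bound`) or strongly associated by odds ratio
#' (`OR > or_high` or `OR < or_low`). All inequalities are strict.
#'
#' @param stats Tibble from [compute_feature_stats()].
#' @param min_prevalence Prevalence gate (default 0.01).
#' @param phi_bound Correlation bound (default 0.05).
#' @param or_high,or_low Odds-ratio bounds (defaults 2.0 and 0.5).
#' @return The input tibble with a logical `selected` column.
#' @export
select_features <- function(stats, min_prevalence = 0.01, phi_bound = 0.05,
                            or_high = 2.0, or_low = 0.5) {
  stopifnot(or_low < 1, or_high > 1)
  dplyr::mutate(
    stats,
    selected = (.data$prev_case > min_prevalence |
                  .data$prev_ctrl > min_prevalence) &
      (abs(.data$phi) > phi_bound |
         .data$odds_ratio > or_high | .data$odds_ratio < or_low)
  )
}
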