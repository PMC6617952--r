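#' Specify a synthetic matched case/control cohort
#'
#' Describes a cohort of older adults with a coded dementia diagnosis (cases)
#' and matched comparison subjects without one (controls). Controls are
#' matched 5:1 by default on gender, age within 5 years, and Charlson
#' comorbidity index (CCI) category, mirroring common specialty-clinic
#' phenotyping cohorts. Each subject's structured and note data live in a
#' fixed observation window that ends the day before the index date.
#'
#' @param n_cases Number of cases.
#' @param control_ratio Matched controls per case (default 5).
#' @param age_range Two-element integer vector, inclusive age range at index.
#' @param gender_mix Proportion male in `[0, 1]`.
#' @param cci_probs Named probabilities over the CCI categories
#'   `"0"`, `"1-2"`, `"3-4"`, `">4"`; must sum to 1.
#' @param window_days Length of the observation window in days (default 1095,
#'   i.e. three years).
#' @param index_origin Earliest possible index date.
#' @param index_span_days Number of days over which index dates are spread.
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' cohort_spec(n_cases = 10)
cohort_spec <- function(n_cases,
                        control_ratio = 5,
                        age_range = c(65L, 95L),
                        gender_mix = 0.95,
                        cci_probs = c("0" = 0.35, "1-2" = 0.30,
                                      "3-4" = 0.20, ">4" = 0.15),
                        window_days = 1095,
                        index_origin = as.Date("2012-01-01"),
                        index_span_days = 1460) {
  n_cases <- check_count(n_cases, "n_cases")
  control_ratio <- check_count(control_ratio, "control_ratio")
  window_days <- check_count(window_days, "window_days")
  check_prob(gender_mix, "gender_mix")
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    stop("`age_range` must be an increasing pair of ages", call. = FALSE)
  }
  if (is.null(names(cci_probs)) || any(!nzchar(names(cci_probs)))) {
    stop("`cci_probs` must be a named probability vector", call. = FALSE)
  }
  if (any(cci_probs < 0) || abs(sum(cci_probs) - 1) > 1e-8) {
    stop("`cci_probs` must be non-negative and sum to 1", call. = FALSE)
  }
  if (all(cci_probs == 0)) {
    stop("at least one CCI category must have positive probability",
         call. = FALSE)
  }
  structure(
    list(n_cases = n_cases, control_ratio = control_ratio,
         age_range = as.integer(age_range), gender_mix = gender_mix,
         cci_probs = cci_probs, window_days = window_days,
         index_origin = index_origin,
         index_span_days = as.integer(index_span_days)),
    class = "cohort_spec"
  )
}

#' Generate a matched case/control cohort
#'
#' Cases are drawn from the specified demographic mix; each case then gets
#' `control_ratio` constructed matches with identical gender and CCI category
#' and an age within 5 years. Matching is constructed rather than solved as an
#' assignment problem: the generator's contract is that the stated matching
#' constraints hold, not that matching was performed against a candidate pool.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (`"case"`/`"control"`), `matched_case` (the case a control is matched to,
#'   `NA` for cases), `gender`, `age`, `cci_category`, `index_date`.
#' @export
#' @examples
#' generate_cohort(cohort_spec(n_cases = 3), seed = 1)
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_cases
    case_id <- sprintf("case_%04d", seq_len(n))
    gender <- ifelse(runif(n) < spec$gender_mix, "M", "F")
    age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
    cci <- sample(names(spec$cci_probs), n, replace = TRUE,
                  prob = spec$cci_probs)
    index <- spec$index_origin +
      sample.int(spec$index_span_days, n, replace = TRUE) - 1L

    cases <- tibble::tibble(
      subject_id = case_id, group = "case", matched_case = NA_character_,
      gender = gender, age = age, cci_category = cci, index_date = index
    )

    r <- spec$control_ratio
    idx <- rep(seq_len(n), each = r)
    ctrl <- tibble::tibble(
      subject_id = sprintf("ctrl_%04d_%d", idx, rep(seq_len(r), times = n)),
      group = "control",
      matched_case = case_id[idx],
      gender = gender[idx],
      age = pmin(pmax(age[idx] + sample(-5:5, n * r, replace = TRUE),
                      spec$age_range[1] - 5L), spec$age_range[2] + 5L),
      cci_category = cci[idx],
      index_date = spec$index_origin +
        sample.int(spec$index_span_days, n * r, replace = TRUE) - 1L
    )
    dplyr::bind_rows(cases, ctrl)
  })
}

#' Plant a latent undiagnosed-dementia signal among controls
#'
#' Each control receives a latent severity score drawn uniformly on `[0, 1]`
#' and a ground-truth undiagnosed-dementia flag drawn with probability
#' `slope_b_true * latent_score` (clamped to `[0, 1]`). The planted
#' relationship is exactly the zero-intercept rate line the calibration stage
#' fits, so binning controls by latent severity recovers `slope_b_true`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param slope_b_true Slope of the planted linear undiagnosed-rate model,
#'   in `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble of controls: `subject_id`, `latent_score`,
#'   `true_undiagnosed` (logical).
#' @export
plant_undiagnosed <- function(cohort, slope_b_true = 0.5, seed = 1) {
  check_prob(slope_b_true, "slope_b_true")
  ctrl <- dplyr::filter(cohort, .data$group == "control")
  withr::with_seed(seed, {
    s <- runif(nrow(ctrl))
    u <- rbinom(nrow(ctrl), 1L, pmin(pmax(slope_b_true * s, 0), 1)) == 1L
    tibble::tibble(subject_id = ctrl$subject_id, latent_score = s,
                   true_undiagnosed = u)
  })
}
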