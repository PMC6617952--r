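#' Default structured-event prevalence profile
#'
#' A per-code Bernoulli presence profile spanning the four structured domains
#' (ICD diagnosis codes, CPT procedure codes, medications, note types), with
#' dementia-associated codes more prevalent among affected subjects,
#' null codes equally prevalent, and a few codes protective. The dementia ICD
#' codes and anti-dementia medications themselves are carried with zero
#' prevalence for everyone: the observation window precedes the first coded
#' diagnosis for cases, and controls are undiagnosed and untreated by
#' construction.
#'
#' @return An `event_profile` list: a `codes` tibble
#'   (`domain`, `code`, `prev_case`, `prev_ctrl`), plus the exclusion sets
#'   `dementia_icd_codes` and `antidementia_meds`.
#' @export
default_event_profile <- function() {
  dementia_icd <- c("331.0", "290.0", "290.10", "290.11", "290.12", "290.13",
                    "290.20", "290.21", "290.3", "290.40", "294.10", "294.11")
  antidementia <- c("donepezil", "galantamine", "rivastigmine", "memantine")

  codes <- tibble::tribble(
    ~domain,    ~code,            ~prev_case, ~prev_ctrl,
    # dementia-adjacent symptoms / work-up: enriched in affected subjects
    "ICD",      "780.93",         0.55,       0.10,   # memory loss
    "ICD",      "799.59",         0.30,       0.06,   # cognitive sign NEC
    "ICD",      "298.9",          0.20,       0.05,
    "ICD",      "311",            0.40,       0.22,   # depression
    "ICD",      "401.9",          0.60,       0.55,   # hypertension (null-ish)
    "ICD",      "250.00",         0.30,       0.28,
    "ICD",      "715.90",         0.25,       0.27,
    "ICD",      "786.50",         0.10,       0.18,   # protective-direction
    "CPT",      "96116",          0.45,       0.05,   # neurobehavioural exam
    "CPT",      "96118",          0.25,       0.03,   # neuropsych testing
    "CPT",      "99213",          0.85,       0.80,
    "CPT",      "93000",          0.30,       0.32,
    "CPT",      "99406",          0.08,       0.15,
    "MED",      "sertraline",     0.30,       0.12,
    "MED",      "quetiapine",     0.18,       0.04,
    "MED",      "trazodone",      0.25,       0.08,
    "MED",      "lisinopril",     0.45,       0.44,
    "MED",      "atorvastatin",   0.50,       0.48,
    "MED",      "metformin",      0.22,       0.24,
    "NOTETYPE", "NEUROLOGY",      0.50,       0.08,
    "NOTETYPE", "SOCIAL WORK",    0.35,       0.12,
    "NOTETYPE", "PRIMARY CARE",   0.90,       0.88,
    "NOTETYPE", "NURSING",        0.60,       0.58
  )
  excl <- dplyr::bind_rows(
    tibble::tibble(domain = "ICD", code = dementia_icd,
                   prev_case = 0, prev_ctrl = 0),
    tibble::tibble(domain = "MED", code = antidementia,
                   prev_case = 0, prev_ctrl = 0)
  )
  structure(
    list(codes = dplyr::bind_rows(codes, excl),
         dementia_icd_codes = dementia_icd,
         antidementia_meds = antidementia),
    class = "event_profile"
  )
}

#' Generate structured EHR events
#'
#' Presence of each (domain, code) pair is Bernoulli per subject with the
#' profile's group prevalence; affected subjects (cases and planted
#' undiagnosed controls) use `prev_case`, other controls `prev_ctrl`.
#' A present code receives one event dated uniformly in the subject's
#' observation window `[index_date - window_days, index_date)`. No control
#' ever receives a dementia ICD code or an anti-dementia medication,
#' whatever the profile says: being undiagnosed and untreated is what defines
#' the control group.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param profile An `event_profile`, e.g. [default_event_profile()].
#' @param signal Planted-signal tibble from [plant_undiagnosed()].
#' @param window_days Observation window length in days.
#' @param seed Integer seed.
#' @return A tibble of events: `subject_id`, `event_date`, `domain`, `code`.
#' @export
generate_structured_events <- function(cohort, profile = default_event_profile(),
                                       signal = NULL, window_days = 1095,
                                       seed = 1) {
  stopifnot(inherits(profile, "event_profile"))
  codes <- profile$codes
  if (any(codes$prev_case < 0 | codes$prev_case > 1 |
          codes$prev_ctrl < 0 | codes$prev_ctrl > 1)) {
    stop("profile prevalences must lie in [0, 1]", call. = FALSE)
  }
  affected <- affected_subjects(cohort, signal)
  is_excluded <- (codes$domain == "ICD" &
                    codes$code %in% profile$dementia_icd_codes) |
                 (codes$domain == "MED" &
                    codes$code %in% profile$antidementia_meds)

  withr::with_seed(seed, {
    n_subj <- nrow(cohort)
    n_code <- nrow(codes)
    p <- matrix(0, n_subj, n_code)
    aff <- affected[cohort$subject_id]
    for (j in seq_len(n_code)) {
      p[, j] <- ifelse(aff, codes$prev_case[j], codes$prev_ctrl[j])
      if (is_excluded[j]) p[cohort$group == "control", j] <- 0
    }
    present <- matrix(runif(n_subj * n_code) < p, n_subj, n_code)
    idx <- which(present, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(tibble::tibble(subject_id = character(), event_date = as.Date(character()),
                            domain = character(), code = character()))
    }
    offs <- sample.int(window_days, nrow(idx), replace = TRUE)
    tibble::tibble(
      subject_id = cohort$subject_id[idx[, 1]],
      event_date = cohort$index_date[idx[, 1]] - offs,
      domain = codes$domain[idx[, 2]],
      code = codes$code[idx[, 2]]
    ) |>
      dplyr::arrange(.data$subject_id, .data$event_date, .data$domain,
                     .data$code)
  })
}

#' Simulate an expert chart review of controls
#'
#' A stand-in for specialist record review: truly undiagnosed controls are
#' labelled `"Dementia"` with probability `sens_review`, truly negative
#' controls are labelled `"Non-Dementia"` with probability `spec_review`,
#' and any verdict is independently replaced by `"Unclear"` with probability
#' `p_unclear` (mimicking charts with insufficient information).
#'
#' @param controls Tibble of controls to review (needs `subject_id`).
#' @param signal Planted-signal tibble from [plant_undiagnosed()].
#' @param sens_review Reviewer sensitivity in `[0, 1]`.
#' @param spec_review Reviewer specificity in `[0, 1]`.
#' @param p_unclear Probability a verdict is replaced by `"Unclear"`.
#' @param seed Integer seed.
#' @return A tibble: `subject_id`, `review_label` in
#'   `{"Dementia", "Unclear", "Non-Dementia"}`.
#' @export
simulate_chart_review <- function(controls, signal,
                                  sens_review = 0.9, spec_review = 0.95,
                                  p_unclear = 0.05, seed = 1) {
  check_prob(sens_review, "sens_review")
  check_prob(spec_review, "spec_review")
  check_prob(p_unclear, "p_unclear")
  truth <- signal$true_undiagnosed[match(controls$subject_id,
                                         signal$subject_id)]
  if (anyNA(truth)) {
    stop("every reviewed subject must appear in `signal`", call. = FALSE)
  }
  withr::with_seed(seed, {
    n <- nrow(controls)
    verdict <- ifelse(
      truth,
      ifelse(runif(n) < sens_review, "Dementia", "Non-Dementia"),
      ifelse(runif(n) < spec_review, "Non-Dementia", "Dementia")
    )
    verdict[runif(n) < p_unclear] <- "Unclear"
    tibble::tibble(subject_id = controls$subject_id, review_label = verdict)
  })
}
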