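#' Generate synthetic clinical notes
#'
#' Notes are sampled over each subject's observation window
#' `[index_date - window_days, index_date)`; the index date itself is
#' excluded, matching a design where the window immediately precedes but does
#' not include the first coded diagnosis. The number of notes on each calendar
#' day is Poisson with rate `notes_per_day_rate`; for cases, note days are
#' topped up so that every year of the window has at least `min_days_per_year`
#' distinct note days, reflecting the usual visit-frequency inclusion rule.
#' Note tokens are drawn topic-then-word from the subject's mixing
#' distribution: cases and truly undiagnosed controls use the affected
#' mixing, other controls the base mixing.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param model A [ground_truth_topics()] object.
#' @param signal Planted-signal tibble from [plant_undiagnosed()].
#' @param notes_per_day_rate Poisson rate of notes per calendar day.
#' @param note_length Tokens per note.
#' @param note_concentration Dirichlet concentration of per-note topic
#'   proportions around the subject's mixing distribution: each note draws
#'   its own proportions from `Dirichlet(note_concentration * mixing)`, so
#'   individual notes focus on a few of the subject's themes while the
#'   subject-level average stays at the mixing distribution. `Inf` makes
#'   every note use the mixing distribution exactly.
#' @param window_days Observation window length in days.
#' @param min_days_per_year Minimum distinct note days per year for cases.
#' @param note_types Character vector of note-type labels to sample from.
#' @param seed Integer seed.
#' @return A tibble of notes: `subject_id`, `note_date`, `note_type`, `text`.
#' @export
generate_notes <- function(cohort, model, signal,
                           notes_per_day_rate = 0.02,
                           note_length = 60,
                           note_concentration = 1,
                           window_days = 1095,
                           min_days_per_year = 2,
                           note_types = c("PRIMARY CARE", "NURSING",
                                          "NEUROLOGY", "SOCIAL WORK"),
                           seed = 1) {
  stopifnot(inherits(model, "ground_truth_topics"))
  if (length(model$vocabulary) == 0) stop("empty vocabulary", call. = FALSE)
  note_length <- check_count(note_length, "note_length")
  affected <- affected_subjects(cohort, signal)
  n_years <- ceiling(window_days / 365)

  withr::with_seed(seed, {
    out <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      subj <- cohort$subject_id[i]
      # days-before-index offsets, 1 .. window_days (index day excluded)
      n_notes_day <- rpois(window_days, notes_per_day_rate)
      if (cohort$group[i] == "case") {
        for (y in seq_len(n_years)) {
          days_y <- seq.int((y - 1) * 365 + 1, min(y * 365, window_days))
          have <- sum(n_notes_day[days_y] > 0)
          if (have < min_days_per_year) {
            empty <- days_y[n_notes_day[days_y] == 0]
            add <- sample(empty, min_days_per_year - have)
            n_notes_day[add] <- 1L
          }
        }
      }
      offs <- rep.int(seq_len(window_days), n_notes_day)
      n_i <- length(offs)
      if (n_i == 0) { out[[i]] <- NULL; next }
      mix <- if (affected[subj]) model$affected_mixing else model$base_mixing
      # per-note topic proportions around the subject mixture, then all
      # token topics, then words in bulk per topic (one multinomial draw
      # per topic, not per token)
      z <- integer(n_i * note_length)
      for (j in seq_len(n_i)) {
        theta <- if (is.finite(note_concentration)) {
          g <- rgamma(model$n_topics, shape = note_concentration * mix)
          if (sum(g) == 0) mix else g / sum(g)
        } else {
          mix
        }
        z[((j - 1) * note_length + 1):(j * note_length)] <-
          sample.int(model$n_topics, note_length, replace = TRUE,
                     prob = theta)
      }
      words <- character(length(z))
      for (k in unique(z)) {
        sel <- z == k
        words[sel] <- model$vocabulary[
          sample.int(length(model$vocabulary), sum(sel), replace = TRUE,
                     prob = model$topic_word[k, ])]
      }
      texts <- vapply(split(words, rep(seq_len(n_i), each = note_length)),
                      paste, character(1), collapse = " ")
      out[[i]] <- tibble::tibble(
        subject_id = subj,
        note_date = cohort$index_date[i] - offs,
        note_type = sample(note_types, n_i, replace = TRUE),
        text = texts
      )
    }
    dplyr::arrange(dplyr::bind_rows(out), .data$subject_id, .data$note_date)
  })
}

# Named logical vector: does this subject express the affected (dementia)
# note/event profile? Cases always; controls only when planted undiagnosed.
affected_subjects <- function(cohort, signal) {
  aff <- setNames(cohort$group == "case", cohort$subject_id)
  if (!is.null(signal) && nrow(signal) > 0) {
    aff[signal$subject_id[signal$true_undiagnosed]] <- TRUE
  }
  aff
}
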