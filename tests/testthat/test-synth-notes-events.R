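make_small_world <- function(n_cases = 6, seed = 5, b = 0.6) {
  co <- generate_cohort(cohort_spec(n_cases = n_cases), seed = seed)
  sig <- plant_undiagnosed(co, slope_b_true = b, seed = seed + 1)
  tm <- ground_truth_topics(n_topics = 6, vocab_size = 120,
                            n_dementia_topics = 2, seed = seed + 2)
  list(cohort = co, signal = sig, truth = tm)
}

test_that("note dates lie in the half-open window before the index date", {
  w <- make_small_world()
  notes <- generate_notes(w$cohort, w$truth, w$signal, seed = 8)
  idx <- w$cohort$index_date[match(notes$subject_id, w$cohort$subject_id)]
  expect_true(all(notes$note_date < idx))
  expect_true(all(notes$note_date >= idx - 1095))
})

test_that("cases have at least 2 distinct note days in every window year", {
  w <- make_small_world(n_cases = 10, seed = 21)
  notes <- generate_notes(w$cohort, w$truth, w$signal,
                          notes_per_day_rate = 0.003, seed = 9)
  cases <- w$cohort[w$cohort$group == "case", ]
  for (r in seq_len(nrow(cases))) {
    nd <- unique(notes$note_date[notes$subject_id == cases$subject_id[r]])
    off <- as.integer(cases$index_date[r] - nd)  # 1..1095
    yr <- (off - 1) %/% 365
    expect_true(all(table(factor(yr, levels = 0:2)) >= 2))
  }
})

test_that("zero base mass on dementia topics keeps their anchor words out of control notes", {
  co <- generate_cohort(cohort_spec(n_cases = 4), seed = 31)
  sig <- plant_undiagnosed(co, slope_b_true = 0, seed = 32)  # no undiagnosed
  tm <- ground_truth_topics(n_topics = 5, vocab_size = 100,
                            n_dementia_topics = 1, base_mass = 0,
                            anchor_mass = 1 - 1e-12, seed = 33)
  notes <- generate_notes(co, tm, sig, seed = 34)
  ctrl_notes <- notes[grepl("^ctrl", notes$subject_id), ]
  toks <- unlist(tokenize(ctrl_notes$text))
  # with anchor_mass ~ 1, topic 1's word support is its anchor block only
  anchor1 <- tm$vocabulary[tm$topic_word[1, ] > 1e-6]
  expect_length(intersect(toks, anchor1), 0)
})

test_that("token word frequencies match the mixing-implied multinomial", {
  tm <- ground_truth_topics(n_topics = 6, vocab_size = 120,
                            n_dementia_topics = 2, seed = 41)
  co <- tibble::tibble(subject_id = "case_0001", group = "case",
                       matched_case = NA_character_, gender = "M", age = 80,
                       cci_category = "0", index_date = as.Date("2015-06-01"))
  sig <- tibble::tibble(subject_id = character(), latent_score = numeric(),
                        true_undiagnosed = logical())
  notes <- generate_notes(co, tm, sig, notes_per_day_rate = 0.2,
                          note_length = 80, note_concentration = Inf,
                          seed = 42)
  toks <- unlist(tokenize(notes$text))
  n <- length(toks)
  expect_gt(n, 10000)
  # expected word distribution under the affected mixing
  p <- drop(tm$affected_mixing %*% tm$topic_word)
  # check the aggregate mass on the dementia-topic anchor halves
  sel <- tm$vocabulary[order(tm$topic_word[1, ], decreasing = TRUE)[1:20]]
  p_sel <- sum(p[match(sel, tm$vocabulary)])
  obs <- mean(toks %in% sel)
  expect_lt(abs(obs - p_sel), 3 * sqrt(p_sel * (1 - p_sel) / n))
})

test_that("note generation is reproducible and needs a vocabulary", {
  w <- make_small_world(n_cases = 3, seed = 51)
  a <- generate_notes(w$cohort, w$truth, w$signal, seed = 52)
  b <- generate_notes(w$cohort, w$truth, w$signal, seed = 52)
  expect_identical(a, b)
  bad <- w$truth
  bad$vocabulary <- character(0)
  expect_error(generate_notes(w$cohort, bad, w$signal, seed = 52),
               "vocabulary")
})

test_that("controls never receive dementia codes or anti-dementia medication", {
  w <- make_small_world(n_cases = 30, seed = 61, b = 1)
  prof <- default_event_profile()
  # force nonzero profile prevalences on the exclusion codes: the generator
  # must still zero them for controls (undiagnosed by construction)
  excl <- (prof$codes$domain == "ICD" &
             prof$codes$code %in% prof$dementia_icd_codes) |
          (prof$codes$domain == "MED" &
             prof$codes$code %in% prof$antidementia_meds)
  prof$codes$prev_case[excl] <- 0.5
  prof$codes$prev_ctrl[excl] <- 0.5
  ev <- generate_structured_events(w$cohort, prof, w$signal, seed = 62)
  ctrl_ev <- ev[grepl("^ctrl", ev$subject_id), ]
  expect_false(any(ctrl_ev$domain == "ICD" &
                     ctrl_ev$code %in% prof$dementia_icd_codes))
  expect_false(any(ctrl_ev$domain == "MED" &
                     ctrl_ev$code %in% prof$antidementia_meds))
  # cases may carry them when the profile says so
  case_ev <- ev[grepl("^case", ev$subject_id), ]
  expect_true(any(case_ev$code %in% prof$dementia_icd_codes))
})

test_that("event prevalence matches the profile within binomial error", {
  co <- generate_cohort(cohort_spec(n_cases = 1000, control_ratio = 1),
                        seed = 71)
  sig <- plant_undiagnosed(co, slope_b_true = 0, seed = 72)
  prof <- default_event_profile()
  prof$codes <- tibble::tibble(domain = "ICD", code = c("X1", "X2"),
                               prev_case = c(0.5, 0.2),
                               prev_ctrl = c(0.1, 0))
  ev <- generate_structured_events(co, prof, sig, seed = 73)
  n_case <- sum(co$group == "case")
  obs <- sum(ev$code == "X1" & grepl("^case", ev$subject_id)) / n_case
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.5 * 0.5 / n_case))
  # zero control prevalence means no control carries the code
  expect_false(any(ev$code == "X2" & grepl("^ctrl", ev$subject_id)))
  # dates in window
  idx <- co$index_date[match(ev$subject_id, co$subject_id)]
  expect_true(all(ev$event_date < idx & ev$event_date >= idx - 1095))
})

test_that("the chart-review simulator honours its error rates", {
  co <- generate_cohort(cohort_spec(n_cases = 200), seed = 81)
  sig <- plant_undiagnosed(co, slope_b_true = 1, seed = 82)
  ctrl <- co[co$group == "control", ]

  # noiseless reviewer reproduces ground truth
  rv <- simulate_chart_review(ctrl, sig, sens_review = 1, spec_review = 1,
                              p_unclear = 0, seed = 83)
  truth <- sig$true_undiagnosed[match(rv$subject_id, sig$subject_id)]
  expect_identical(rv$review_label,
                   ifelse(truth, "Dementia", "Non-Dementia"))

  # p_unclear = 1 blanks every verdict
  rv2 <- simulate_chart_review(ctrl, sig, p_unclear = 1, seed = 84)
  expect_true(all(rv2$review_label == "Unclear"))

  # sens_review = 0.9: positives reviewed Dementia-or-Unclear at ~0.9 + noise
  pos <- ctrl[truth, ]
  rv3 <- simulate_chart_review(pos, sig, sens_review = 0.9, spec_review = 1,
                               p_unclear = 0, seed = 85)
  n <- nrow(pos)
  obs <- mean(rv3$review_label == "Dementia")
  expect_lt(abs(obs - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})
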