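#' Pipeline configuration
#'
#' Collects every stage parameter and seed of the end-to-end synthetic
#' pipeline. All randomness is explicitly seeded: stage seeds are derived
#' deterministically from `seed` unless supplied, and the three LDA seeds
#' must be distinct. The defaults describe a desk-scale study: 100 cases
#' with 5:1 matched controls (600 subjects), a 3-year window, a 20-topic
#' ground-truth model with 3 dementia-related topics, and a planted
#' undiagnosed rate rising linearly with latent severity at slope 0.5.
#'
#' @param seed Base seed from which stage seeds are derived.
#' @param n_cases,control_ratio Cohort size parameters.
#' @param slope_b_true Planted zero-intercept slope in `[0, 1]`.
#' @param n_topics_truth,vocab_size,n_dementia_topics Ground-truth topic
#'   model shape.
#' @param notes_per_day_rate,note_length Note generation intensity.
#' @param window_days Observation window length in days.
#' @param n_topics,lda_iterations,infer_iterations,infer_burnin LDA fitting
#'   and inference settings.
#' @param lda_seeds Exactly 3 distinct seeds for the LDA runs.
#' @param similarity_threshold Stable-topic cosine threshold.
#' @param proportion_threshold,quorum Note-level presence rule.
#' @param min_doc_freq Vocabulary document-frequency floor.
#' @param sens_review,spec_review,p_unclear Chart-review simulator.
#' @param target_bin_size Fine-bin target size.
#' @param lambda Ridge penalty of the risk model.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            n_cases = 100, control_ratio = 5,
                            slope_b_true = 0.5,
                            n_topics_truth = 20, vocab_size = 500,
                            n_dementia_topics = 3,
                            notes_per_day_rate = 0.02, note_length = 60,
                            window_days = 1095,
                            n_topics = 20, lda_iterations = 150,
                            infer_iterations = 60, infer_burnin = 20,
                            lda_seeds = NULL,
                            similarity_threshold = 0.8,
                            proportion_threshold = 0.02, quorum = 2,
                            min_doc_freq = 2,
                            sens_review = 0.9, spec_review = 0.95,
                            p_unclear = 0.05,
                            target_bin_size = 100,
                            lambda = 1e-6) {
  if (is.null(lda_seeds)) {
    lda_seeds <- child_seed(seed, c(301, 302, 303))
  }
  if (length(lda_seeds) != 3 || anyDuplicated(lda_seeds)) {
    stop("`lda_seeds` must be exactly 3 distinct integers", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    seed_cohort = child_seed(seed, 101), seed_signal = child_seed(seed, 102),
    seed_notes = child_seed(seed, 103), seed_events = child_seed(seed, 104),
    seed_sample_notes = child_seed(seed, 105),
    seed_infer = child_seed(seed, 106),
    seed_review_sample = child_seed(seed, 107),
    seed_review = child_seed(seed, 108),
    n_cases = n_cases, control_ratio = control_ratio,
    slope_b_true = slope_b_true,
    n_topics_truth = n_topics_truth, vocab_size = vocab_size,
    n_dementia_topics = n_dementia_topics,
    notes_per_day_rate = notes_per_day_rate, note_length = note_length,
    window_days = window_days,
    n_topics = n_topics, lda_iterations = lda_iterations,
    infer_iterations = infer_iterations, infer_burnin = infer_burnin,
    lda_seeds = as.integer(lda_seeds),
    similarity_threshold = similarity_threshold,
    proportion_threshold = proportion_threshold, quorum = quorum,
    min_doc_freq = min_doc_freq,
    sens_review = sens_review, spec_review = spec_review,
    p_unclear = p_unclear,
    target_bin_size = target_bin_size, lambda = lambda
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-to-ROC pipeline
#'
#' Executes, in order: cohort simulation, planted signal, note and event
#' generation, one-note-per-day sampling, tokenization/encoding, three LDA
#' runs, stable-topic extraction, topic and structured feature construction,
#' feature selection, risk-model fitting, scoring, stratified chart review,
#' rate computation and line fitting under both Unclear policies,
#' fine binning, per-bin undiagnosed estimation, and ROC/AUC. Each stage
#' logs its input/output record counts; rerunning with the same
#' configuration reproduces every artifact exactly.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage messages (default TRUE).
#' @return A named list with every intermediate and final artifact, among
#'   them `cohort`, `signal`, `notes`, `events`, `corpus`, `models`,
#'   `stable`, `features`, `feature_stats`, `risk_model`, `scores`,
#'   `review`, `rates`, `rate_fits`, `partition`, `roc` (one per policy),
#'   `thresholds`, and `ground_truth_auc`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  cfg <- config

  spec <- cohort_spec(n_cases = cfg$n_cases, control_ratio = cfg$control_ratio,
                      window_days = cfg$window_days)
  cohort <- generate_cohort(spec, seed = cfg$seed_cohort)
  say("simulate", "cohort: %d cases, %d controls",
      sum(cohort$group == "case"), sum(cohort$group == "control"))

  signal <- plant_undiagnosed(cohort, slope_b_true = cfg$slope_b_true,
                              seed = cfg$seed_signal)
  say("simulate", "planted undiagnosed controls: %d of %d",
      sum(signal$true_undiagnosed), nrow(signal))

  truth <- ground_truth_topics(n_topics = cfg$n_topics_truth,
                               vocab_size = cfg$vocab_size,
                               n_dementia_topics = cfg$n_dementia_topics,
                               seed = cfg$seed)
  notes <- generate_notes(cohort, truth, signal,
                          notes_per_day_rate = cfg$notes_per_day_rate,
                          note_length = cfg$note_length,
                          window_days = cfg$window_days,
                          seed = cfg$seed_notes)
  say("simulate", "notes: %d", nrow(notes))

  events <- generate_structured_events(cohort, default_event_profile(),
                                       signal,
                                       window_days = cfg$window_days,
                                       seed = cfg$seed_events)
  say("simulate", "structured events: %d", nrow(events))

  sampled <- sample_one_note_per_day(notes, seed = cfg$seed_sample_notes)
  say("preprocess", "notes in: %d, one per subject-day: %d",
      nrow(notes), nrow(sampled))
  corpus <- encode_corpus(sampled, min_doc_freq = cfg$min_doc_freq)
  say("preprocess", "vocabulary: %d words, %d tokens",
      nrow(corpus$vocabulary), sum(lengths(corpus$documents)))

  models <- fit_lda_multi(corpus, n_topics = cfg$n_topics,
                          seeds = cfg$lda_seeds,
                          n_iterations = cfg$lda_iterations)
  say("lda", "3 runs of %d topics, %d iterations each",
      cfg$n_topics, cfg$lda_iterations)

  stable <- extract_stable_topics(models,
                                  similarity_threshold =
                                    cfg$similarity_threshold)
  say("stable-topics", "stable topics: %d of %d", nrow(stable), cfg$n_topics)

  props <- lapply(seq_along(models), function(r) {
    infer_topic_proportions(models[[r]], corpus,
                            n_iterations = cfg$infer_iterations,
                            burnin = cfg$infer_burnin,
                            seed = child_seed(cfg$seed_infer, r))
  })
  note_pres <- note_topic_presence(stable, props,
                                   proportion_threshold =
                                     cfg$proportion_threshold,
                                   quorum = cfg$quorum)
  topic_pres <- subject_topic_presence(note_pres, corpus$doc_meta,
                                       subject_ids = cohort$subject_id)

  structured <- aggregate_structured(events, cohort,
                                     window_days = cfg$window_days)
  features <- build_feature_matrix(structured, topic_pres)
  say("features", "candidate features: %d", ncol(features) - 1)

  stats <- compute_feature_stats(features, cohort) |> select_features()
  selected <- stats$feature[stats$selected]
  say("features", "selected features: %d", length(selected))
  feat_sel <- features[, c("subject_id", selected)]

  model <- fit_risk_model(feat_sel, cohort, lambda = cfg$lambda)
  scores <- predict_risk_scores(feat_sel, model, cohort)
  say("score", "scored %d subjects", nrow(scores))

  ctrl_scores <- dplyr::filter(scores, .data$group == "control")
  sampled_ctrl <- draw_review_sample(ctrl_scores,
                                     seed = cfg$seed_review_sample)
  review <- simulate_chart_review(sampled_ctrl, signal,
                                  sens_review = cfg$sens_review,
                                  spec_review = cfg$spec_review,
                                  p_unclear = cfg$p_unclear,
                                  seed = cfg$seed_review)
  reviewed <- dplyr::inner_join(sampled_ctrl, review, by = "subject_id")
  say("calibrate", "reviewed controls: %d", nrow(reviewed))

  counts <- tally_review(reviewed)
  rates <- compute_rates(counts)
  rate_fits <- rates |>
    split(~policy) |>
    lapply(function(df) fit_rate_line(df$rate, df$midpoint))
  for (pol in names(rate_fits)) {
    say("calibrate", "%s: zero-intercept slope %.3f (intercept p = %.3f)",
        pol, rate_fits[[pol]]$slope_zero, rate_fits[[pol]]$p_value[1])
  }

  partition <- partition_controls(ctrl_scores$score,
                                  target_size = cfg$target_bin_size)
  roc <- lapply(rate_fits, function(f) {
    roc_curve(estimate_undiagnosed(partition, min(1, f$slope_zero)))
  })
  thresholds <- lapply(roc, pick_thresholds)
  for (pol in names(roc)) {
    say("roc", "%s: %d bins, AUC = %.3f", pol, nrow(partition),
        attr(roc[[pol]], "auc"))
  }

  gt_auc <- empirical_auc(
    ctrl_scores$score,
    signal$true_undiagnosed[match(ctrl_scores$subject_id,
                                  signal$subject_id)])
  say("roc", "AUC of score against planted ground truth: %.3f", gt_auc)

  list(config = cfg, cohort = cohort, signal = signal, truth = truth,
       notes = notes, events = events, sampled_notes = sampled,
       corpus = corpus, models = models, stable = stable,
       proportions = props, topic_presence = topic_pres,
       structured = structured, features = features,
       feature_stats = stats, selected_features = selected,
       risk_model = model, scores = scores, reviewed = reviewed,
       review_counts = counts, rates = rates, rate_fits = rate_fits,
       partition = partition, roc = roc, thresholds = thresholds,
       ground_truth_auc = gt_auc)
}
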