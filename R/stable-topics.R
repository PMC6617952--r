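#' Extract topics that are stable across three LDA runs
#'
#' A topic triple (one topic from each run) is stable when each pair within
#' the triple is a mutual best match by cosine similarity of topic-word
#' distributions and all three pairwise cosines reach `similarity_threshold`.
#' Mutual best matching makes the assignment one-to-one: no run topic can
#' appear in two triples. The merged word distribution is the unweighted mean
#' of the three aligned rows and is used only for labelling and for matching
#' stable topics to external references, never for the presence rule.
#'
#' @param models List of exactly 3 `topic_model` objects sharing one
#'   vocabulary and topic count.
#' @param similarity_threshold Minimum pairwise cosine in `[0, 1]`
#'   (default 0.8).
#' @param n_label_words How many top words label each stable topic.
#' @return A `stable_topics` object: a tibble with `stable_id`, `run1`,
#'   `run2`, `run3` (topic indices per run), `min_pairwise_cosine`, and
#'   `label` (top words of the merged distribution); the merged
#'   topics x vocabulary matrix is in `attr(, "merged_word_dist")`.
#' @export
extract_stable_topics <- function(models, similarity_threshold = 0.8,
                                  n_label_words = 10) {
  if (length(models) != 3 || !all(vapply(models, inherits, TRUE, "topic_model"))) {
    stop("`models` must be a list of exactly 3 topic models", call. = FALSE)
  }
  check_prob(similarity_threshold, "similarity_threshold")
  vocabs <- lapply(models, `[[`, "vocabulary")
  if (!identical(vocabs[[1]], vocabs[[2]]) ||
      !identical(vocabs[[1]], vocabs[[3]])) {
    stop("the three models must share one vocabulary", call. = FALSE)
  }
  K <- models[[1]]$n_topics
  if (models[[2]]$n_topics != K || models[[3]]$n_topics != K) {
    stop("the three models must share one topic count", call. = FALSE)
  }

  s12 <- row_cosine(models[[1]]$topic_word, models[[2]]$topic_word)
  s13 <- row_cosine(models[[1]]$topic_word, models[[3]]$topic_word)
  s23 <- row_cosine(models[[2]]$topic_word, models[[3]]$topic_word)

  mutual_best <- function(S) {
    # pairs (i, j) where j is i's best match and i is j's best match;
    # which.max breaks ties toward the lower index, deterministically
    best_row <- apply(S, 1, which.max)
    best_col <- apply(S, 2, which.max)
    i <- seq_len(nrow(S))
    keep <- best_col[best_row[i]] == i
    cbind(i[keep], best_row[i][keep])
  }

  m12 <- mutual_best(s12)
  m13 <- mutual_best(s13)
  m23 <- mutual_best(s23)
  map12 <- setNames(m12[, 2], m12[, 1])
  map13 <- setNames(m13[, 2], m13[, 1])
  map23 <- setNames(m23[, 2], m23[, 1])

  triples <- list()
  for (i in as.integer(names(map12))) {
    j <- map12[[as.character(i)]]
    k13 <- map13[as.character(i)]
    k23 <- map23[as.character(j)]
    if (is.na(k13) || is.na(k23) || k13 != k23) next
    k <- unname(k13)
    cos3 <- c(s12[i, j], s13[i, k], s23[j, k])
    if (min(cos3) < similarity_threshold) next
    triples[[length(triples) + 1]] <-
      tibble::tibble(run1 = i, run2 = unname(j), run3 = k,
                     min_pairwise_cosine = min(cos3))
  }

  if (length(triples) == 0) {
    out <- tibble::tibble(stable_id = integer(), run1 = integer(),
                          run2 = integer(), run3 = integer(),
                          min_pairwise_cosine = numeric(), label = character())
    merged <- matrix(numeric(), 0, length(vocabs[[1]]),
                     dimnames = list(NULL, vocabs[[1]]))
  } else {
    out <- dplyr::bind_rows(triples) |>
      dplyr::arrange(.data$run1) |>
      dplyr::mutate(stable_id = dplyr::row_number(), .before = 1)
    merged <- (models[[1]]$topic_word[out$run1, , drop = FALSE] +
               models[[2]]$topic_word[out$run2, , drop = FALSE] +
               models[[3]]$topic_word[out$run3, , drop = FALSE]) / 3
    out$label <- apply(merged, 1, function(p) {
      paste(vocabs[[1]][order(p, decreasing = TRUE)[seq_len(n_label_words)]],
            collapse = " ")
    })
  }
  structure(out, merged_word_dist = merged, class = c("stable_topics",
                                                      class(out)))
}

#' Note-level stable-topic presence
#'
#' A stable topic is present in a note when at least `quorum` of its three
#' per-run proportions are greater than or equal to `proportion_threshold`
#' (the boundary is inclusive). The default rule — 2 of 3 proportions at or
#' above 2% — treats a topic as reliably expressed in a note only when a
#' majority of the independent runs agree.
#'
#' @param stable A `stable_topics` object.
#' @param proportions List of 3 matrices (documents x topics), the inferred
#'   proportions under each run's model, in run order.
#' @param proportion_threshold Presence threshold on a proportion
#'   (default 0.02).
#' @param quorum How many of the 3 runs must reach the threshold (default 2).
#' @return A logical matrix (documents x stable topics).
#' @export
note_topic_presence <- function(stable, proportions,
                                proportion_threshold = 0.02, quorum = 2) {
  stopifnot(inherits(stable, "stable_topics"), length(proportions) == 3)
  if (proportion_threshold <= 0 || proportion_threshold >= 1) {
    stop("`proportion_threshold` must lie strictly between 0 and 1",
         call. = FALSE)
  }
  quorum <- check_count(quorum, "quorum")
  if (quorum > 3) stop("`quorum` cannot exceed the 3 runs", call. = FALSE)
  hits <- (proportions[[1]][, stable$run1, drop = FALSE] >=
             proportion_threshold) +
          (proportions[[2]][, stable$run2, drop = FALSE] >=
             proportion_threshold) +
          (proportions[[3]][, stable$run3, drop = FALSE] >=
             proportion_threshold)
  out <- hits >= quorum
  colnames(out) <- paste0("topic_", stable$stable_id)
  out
}

#' Subject-level stable-topic presence
#'
#' A stable topic is present in a subject when it is present in at least one
#' of the subject's notes (logical OR over notes). Subjects listed in
#' `subject_ids` but owning no notes get an all-zero row with a warning.
#'
#' @param presence Logical matrix from [note_topic_presence()]
#'   (documents x stable topics).
#' @param doc_meta The corpus `doc_meta` tibble (with `subject_id` per
#'   document row).
#' @param subject_ids Optional character vector fixing the output subjects
#'   and their order; defaults to the subjects present in `doc_meta`.
#' @return A tibble: `subject_id` plus one 0/1 integer column per stable
#'   topic.
#' @export
subject_topic_presence <- function(presence, doc_meta, subject_ids = NULL) {
  stopifnot(nrow(presence) == nrow(doc_meta))
  if (is.null(subject_ids)) subject_ids <- sort(unique(doc_meta$subject_id))
  agg <- rowsum(presence + 0L, group = doc_meta$subject_id)
  out <- matrix(0L, length(subject_ids), ncol(presence),
                dimnames = list(subject_ids, colnames(presence)))
  found <- intersect(subject_ids, rownames(agg))
  out[found, ] <- (agg[found, , drop = FALSE] > 0) + 0L
  missing <- setdiff(subject_ids, rownames(agg))
  if (length(missing) > 0) {
    warning(sprintf("%d subject(s) have no notes; their topic presence is 0",
                    length(missing)), call. = FALSE)
  }
  tibble::as_tibble(out, rownames = "subject_id")
}
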