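#' Keep one note per subject-day
#'
#' Topic fitting over a large note corpus is expensive and multiple same-day
#' notes are highly redundant, so the corpus is thinned to exactly one
#' uniformly chosen note per (subject, day) pair. The operation is idempotent:
#' applying it to an already-thinned corpus returns it unchanged.
#'
#' @param notes Tibble of notes with `subject_id` and `note_date`.
#' @param seed Integer seed for the uniform within-day choice.
#' @return A tibble with one row per (subject, day), same columns as `notes`.
#' @export
sample_one_note_per_day <- function(notes, seed = 1) {
  stopifnot(all(c("subject_id", "note_date") %in% names(notes)))
  withr::with_seed(seed, {
    notes |>
      dplyr::mutate(.r = runif(dplyr::n())) |>
      dplyr::group_by(.data$subject_id, .data$note_date) |>
      dplyr::slice_min(.data$.r, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".r") |>
      dplyr::arrange(.data$subject_id, .data$note_date)
  })
}

#' Default stopword list
#'
#' A small list of high-frequency English function words removed during
#' tokenization; clinical content words are never stoplisted.
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "from",
    "had", "has", "have", "he", "her", "his", "if", "in", "is", "it", "its",
    "no", "not", "of", "on", "or", "she", "that", "the", "their", "they",
    "this", "to", "was", "were", "will", "with")
}

#' Tokenize free text
#'
#' Lowercases, splits on runs of non-alphanumeric characters, and drops
#' stopwords and tokens shorter than `min_length` characters. Deterministic;
#' empty text yields an empty token vector.
#'
#' @param text Character vector of documents.
#' @param stopwords Character vector of words to drop.
#' @param min_length Minimum token length in characters.
#' @return A list of character vectors, one per input document.
#' @export
#' @examples
#' tokenize("Memory loss; MMSE 22.")
tokenize <- function(text, stopwords = default_stopwords(), min_length = 2) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) {
    t <- t[nchar(t) >= min_length & !t %in% stopwords]
    t[nzchar(t)]
  })
}

#' Build a vocabulary and encode a note corpus
#'
#' Tokenizes every note, drops words appearing in fewer than `min_doc_freq`
#' documents, and encodes each document as a sequence of integer word ids.
#' Ids are assigned in lexicographic word order so the encoding is stable
#' across runs and platforms.
#'
#' @param notes Tibble of notes with `subject_id`, `note_date`, `text`.
#' @param min_doc_freq Drop words occurring in fewer than this many documents.
#' @param stopwords Passed to [tokenize()].
#' @return A `tokenized_corpus` list: `documents` (list of integer id
#'   vectors, 1-based), `vocabulary` tibble (`id`, `word`, `doc_freq`), and
#'   `doc_meta` tibble (`doc_id`, `subject_id`, `note_date`).
#' @export
encode_corpus <- function(notes, min_doc_freq = 2,
                          stopwords = default_stopwords()) {
  min_doc_freq <- check_count(min_doc_freq, "min_doc_freq")
  toks <- tokenize(notes$text, stopwords = stopwords)
  df_counts <- table(unlist(lapply(toks, unique)))
  keep <- sort(names(df_counts)[df_counts >= min_doc_freq])
  if (length(keep) == 0) {
    stop(sprintf("no word appears in at least %d documents (min_doc_freq)",
                 min_doc_freq), call. = FALSE)
  }
  vocab <- tibble::tibble(id = seq_along(keep), word = keep,
                          doc_freq = as.integer(df_counts[keep]))
  ids <- setNames(vocab$id, vocab$word)
  documents <- lapply(toks, function(t) unname(ids[t[t %in% keep]]))
  structure(
    list(documents = documents,
         vocabulary = vocab,
         doc_meta = tibble::tibble(doc_id = seq_along(documents),
                                   subject_id = notes$subject_id,
                                   note_date = notes$note_date)),
    class = "tokenized_corpus"
  )
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("<tokenized_corpus> %d documents, vocabulary %d, %d tokens\n",
              length(x$documents), nrow(x$vocabulary),
              sum(lengths(x$documents))))
  invisible(x)
}
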