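#' Construct a ground-truth topic model for note generation
#'
#' Builds a known topic-word model from which synthetic clinical notes are
#' sampled, so that downstream topic recovery can be checked against planted
#' truth. Each topic concentrates most of its mass (`anchor_mass`) on its own
#' block of anchor words and spreads the remainder uniformly, giving
#' well-separated topics. A subset of topics is designated dementia-related;
#' the affected mixing distribution moves `affected_mass` of topic probability
#' onto those topics, while the base mixing leaves them at `base_mass`.
#'
#' @param n_topics Number of topics (>= 2).
#' @param vocab_size Vocabulary size; must be >= `n_topics`.
#' @param n_dementia_topics How many topics are dementia-related.
#' @param anchor_mass Probability mass a topic puts on its own anchor block.
#' @param base_mass Total mixing mass on dementia topics for unaffected
#'   subjects.
#' @param affected_mass Total mixing mass on dementia topics for affected
#'   subjects (cases and truly undiagnosed controls).
#' @param seed Integer seed (used to jitter topic-word rows).
#' @return A `ground_truth_topics` list with elements `n_topics`,
#'   `vocabulary`, `topic_word` (topics x words, rows sum to 1),
#'   `dementia_topic_ids`, `base_mixing`, `affected_mixing`.
#' @export
ground_truth_topics <- function(n_topics = 20,
                                vocab_size = 500,
                                n_dementia_topics = 3,
                                anchor_mass = 0.85,
                                base_mass = 0.02,
                                affected_mass = 0.35,
                                seed = 1) {
  n_topics <- check_count(n_topics, "n_topics", min = 2)
  vocab_size <- check_count(vocab_size, "vocab_size", min = n_topics)
  n_dementia_topics <- check_count(n_dementia_topics, "n_dementia_topics")
  stopifnot(n_dementia_topics < n_topics)
  check_prob(anchor_mass, "anchor_mass")
  check_prob(base_mass, "base_mass")
  check_prob(affected_mass, "affected_mass")

  # A few recognisable dementia terms lead the vocabulary; the rest are
  # synthetic word ids. Vocabulary is kept lexicographically stable.
  seed_words <- c("memory", "cognitive", "dementia", "alzheimer", "mmse",
                  "recall", "confusion", "orientation", "caregiver", "decline")
  vocabulary <- c(seed_words[seq_len(min(10, vocab_size))],
                  sprintf("w%04d", seq_len(max(0, vocab_size - 10))))

  blocks <- split(seq_len(vocab_size),
                  rep(seq_len(n_topics), length.out = vocab_size))
  withr::with_seed(seed, {
    topic_word <- matrix(0, n_topics, vocab_size)
    for (k in seq_len(n_topics)) {
      w_anchor <- rgamma(length(blocks[[k]]), shape = 5)
      w_rest <- rgamma(vocab_size, shape = 1) * 0.05
      row <- w_rest
      row[blocks[[k]]] <- row[blocks[[k]]] +
        w_anchor / sum(w_anchor) * sum(w_rest) *
          anchor_mass / (1 - anchor_mass)
      topic_word[k, ] <- row / sum(row)
    }
  })
  colnames(topic_word) <- vocabulary

  dementia_ids <- seq_len(n_dementia_topics)
  mixing <- function(mass_on_dementia) {
    m <- rep((1 - mass_on_dementia) / (n_topics - n_dementia_topics), n_topics)
    m[dementia_ids] <- mass_on_dementia / n_dementia_topics
    m
  }
  structure(
    list(n_topics = n_topics, vocabulary = vocabulary,
         topic_word = topic_word, dementia_topic_ids = dementia_ids,
         base_mixing = mixing(base_mass),
         affected_mixing = mixing(affected_mass)),
    class = "ground_truth_topics"
  )
}
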