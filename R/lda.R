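#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Fits latent Dirichlet allocation with a symmetric Dirichlet document-topic
#' prior (total concentration `alpha_sum`, so each topic gets
#' `alpha_sum / n_topics`) and a symmetric topic-word prior `beta`. These
#' defaults mirror widely used toolkit settings (total alpha 5, beta 0.01).
#' The sampler uses its own seeded RNG, so a fit is reproduced exactly by
#' its seed.
#'
#' @param corpus A `tokenized_corpus` from [encode_corpus()].
#' @param n_topics Number of topics (>= 2). Production-scale corpora
#'   typically use on the order of 1000 topics; the package default is 1000,
#'   with much smaller values appropriate for small synthetic corpora.
#' @param alpha_sum Total document-topic concentration.
#' @param beta Topic-word concentration.
#' @param n_iterations Gibbs sweeps.
#' @param seed Integer seed.
#' @return A `topic_model` list: `topic_word` (topics x vocabulary, rows sum
#'   to 1), `vocabulary`, `n_topics`, `alpha`, `beta`, `n_iterations`, `seed`.
#' @export
fit_lda <- function(corpus, n_topics = 1000, alpha_sum = 5, beta = 0.01,
                    n_iterations = 200, seed = 1) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  n_topics <- check_count(n_topics, "n_topics", min = 2)
  if (length(corpus$documents) == 0) stop("empty corpus", call. = FALSE)
  V <- nrow(corpus$vocabulary)
  if (n_topics > V) {
    warning("n_topics exceeds the vocabulary size; some topics will be ",
            "near-empty", call. = FALSE)
  }
  docs0 <- lapply(corpus$documents, function(d) as.integer(d) - 1L)
  fit <- .lda_gibbs_fit(docs0, V, n_topics, alpha_sum / n_topics, beta,
                        as.integer(n_iterations), as.integer(seed))
  tw <- fit$topic_word
  colnames(tw) <- corpus$vocabulary$word
  structure(
    list(topic_word = tw, vocabulary = corpus$vocabulary$word,
         n_topics = n_topics, alpha = alpha_sum / n_topics, beta = beta,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed)),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> %d topics over %d words (seed %d)\n",
              x$n_topics, length(x$vocabulary), x$seed))
  invisible(x)
}

#' Fit LDA several times with distinct seeds
#'
#' Because collapsed Gibbs LDA is stochastic, the recovered topics differ
#' slightly between runs. Fitting the model three times with distinct seeds
#' is the input to stable-topic extraction, which keeps only topics
#' reproduced across all runs.
#'
#' @inheritParams fit_lda
#' @param seeds Integer vector of exactly 3 distinct seeds; models are
#'   returned in seed order.
#' @return A list of 3 `topic_model` objects.
#' @export
fit_lda_multi <- function(corpus, n_topics, seeds, alpha_sum = 5,
                          beta = 0.01, n_iterations = 200) {
  if (length(seeds) != 3 || anyDuplicated(seeds)) {
    stop("`seeds` must be exactly 3 distinct integers", call. = FALSE)
  }
  lapply(seeds, function(s) {
    fit_lda(corpus, n_topics = n_topics, alpha_sum = alpha_sum, beta = beta,
            n_iterations = n_iterations, seed = s)
  })
}

#' Infer per-document topic proportions under a fitted model
#'
#' Runs Gibbs sampling over topic assignments with the model's topic-word
#' distributions frozen, and returns the smoothed posterior mean of the
#' document-topic proportions over the sweeps after burn-in. A document with
#' no in-vocabulary tokens gets the symmetric-prior mean (uniform over
#' topics) with a warning.
#'
#' @param model A `topic_model` from [fit_lda()].
#' @param corpus A `tokenized_corpus` encoded against the same vocabulary.
#' @param n_iterations Gibbs sweeps per document.
#' @param burnin Sweeps discarded before averaging.
#' @param seed Integer seed.
#' @return A numeric matrix (documents x topics); each row sums to 1.
#' @export
infer_topic_proportions <- function(model, corpus, n_iterations = 60,
                                    burnin = 20, seed = 1) {
  stopifnot(inherits(model, "topic_model"),
            inherits(corpus, "tokenized_corpus"))
  if (!identical(model$vocabulary, corpus$vocabulary$word)) {
    stop("corpus vocabulary does not match the model's vocabulary",
         call. = FALSE)
  }
  if (burnin >= n_iterations) stop("`burnin` must be < `n_iterations`",
                                   call. = FALSE)
  if (any(lengths(corpus$documents) == 0)) {
    warning("documents with no in-vocabulary tokens get uniform proportions",
            call. = FALSE)
  }
  docs0 <- lapply(corpus$documents, function(d) as.integer(d) - 1L)
  .lda_gibbs_infer(docs0, model$topic_word, model$alpha,
                   as.integer(n_iterations), as.integer(burnin),
                   as.integer(seed))
}
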