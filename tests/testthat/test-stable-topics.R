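fake_model <- function(topic_word, vocab = NULL) {
  if (is.null(vocab)) vocab <- sprintf("w%03d", seq_len(ncol(topic_word)))
  colnames(topic_word) <- vocab
  structure(list(topic_word = topic_word / rowSums(topic_word),
                 vocabulary = vocab, n_topics = nrow(topic_word),
                 alpha = 0.1, beta = 0.01, n_iterations = 0L, seed = 0L),
            class = "topic_model")
}

test_that("three identical models yield one stable triple per topic", {
  withr::with_seed(1, {
    tw <- matrix(rgamma(8 * 40, 1), 8, 40)
  })
  m <- fake_model(tw)
  st <- extract_stable_topics(list(m, m, m), similarity_threshold = 0.8)
  expect_equal(nrow(st), 8)
  expect_equal(st$run1, st$run2)
  expect_equal(st$run2, st$run3)
  expect_equal(st$min_pairwise_cosine, rep(1, 8), tolerance = 1e-12)
})

test_that("pairwise-orthogonal topics produce no stable triples", {
  # each run's topics live on a disjoint word block, so every cross-run
  # cosine is exactly zero
  block <- function(offset) {
    tw <- matrix(0, 4, 12)
    tw[cbind(1:4, offset + 1:4)] <- 1
    tw
  }
  vocab <- sprintf("w%03d", 1:12)
  ms <- lapply(c(0, 4, 8), function(o) fake_model(block(o), vocab))
  st <- extract_stable_topics(ms, similarity_threshold = 0.5)
  expect_equal(nrow(st), 0)
})

test_that("noisy replicates of a common base are recovered, matching the brute-force search", {
  K <- 10; V <- 60
  withr::with_seed(42, {
    base <- matrix(rgamma(K * V, 0.5), K, V)
    base <- base / rowSums(base)
    perturb <- function(perm) {
      out <- t(apply(base, 1, function(p) {
        g <- rgamma(V, shape = 1000 * p)  # Dirichlet(1000 * p)
        g / sum(g)
      }))
      out[perm, ]
    }
    p2 <- sample(K); p3 <- sample(K)
    m1 <- fake_model(base)
    m2 <- fake_model(perturb(p2))
    m3 <- fake_model(perturb(p3))
  })
  st <- extract_stable_topics(list(m1, m2, m3), similarity_threshold = 0.8)
  expect_equal(nrow(st), K)
  # the aligned triples undo the permutations
  expect_equal(p2[st$run2], st$run1)
  expect_equal(p3[st$run3], st$run1)
  # brute-force greedy max-min-cosine oracle finds the same triples
  bf <- brute_force_triples(m1$topic_word, m2$topic_word, m3$topic_word, 0.8)
  expect_equal(nrow(bf), K)
  expect_equal(bf[order(bf[, 1]), ], cbind(st$run1, st$run2, st$run3),
               ignore_attr = TRUE)
})

test_that("extraction is invariant to topic relabelling within a run", {
  withr::with_seed(9, {
    base <- matrix(rgamma(6 * 30, 1), 6, 30)
  })
  m <- fake_model(base)
  perm <- c(3, 1, 6, 2, 5, 4)
  m_perm <- fake_model(base[perm, ])
  st <- extract_stable_topics(list(m, m, m), 0.8)
  st_p <- extract_stable_topics(list(m, m_perm, m), 0.8)
  expect_equal(nrow(st_p), 6)
  expect_equal(perm[st_p$run2], st_p$run1)
  expect_equal(st_p$run1, st$run1)
})

test_that("stable-topic count is monotone non-increasing in the similarity threshold", {
  corp <- encode_corpus(make_separable_notes(seed = 6), min_doc_freq = 1)
  ms <- fit_lda_multi(corp, 4, seeds = c(1, 2, 3), n_iterations = 60)
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95, 0.999),
                   function(th) nrow(extract_stable_topics(ms, th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(counts <= 4))
})

test_that("mismatched vocabularies are rejected", {
  m1 <- fake_model(matrix(1, 3, 10))
  m2 <- fake_model(matrix(1, 3, 10), vocab = sprintf("v%03d", 1:10))
  expect_error(extract_stable_topics(list(m1, m1, m2)), "vocabulary")
})

test_that("the note presence rule applies an inclusive threshold and quorum", {
  st <- tibble::tibble(stable_id = 1L, run1 = 1L, run2 = 1L, run3 = 1L,
                       min_pairwise_cosine = 1)
  class(st) <- c("stable_topics", class(st))
  pres1 <- function(p) {
    props <- lapply(p, function(x) matrix(x, 1, 1))
    note_topic_presence(st, props)[1, 1]
  }
  expect_true(pres1(c(0.03, 0.025, 0.001)))   # 2 of 3 meet 0.02
  expect_false(pres1(c(0.03, 0.01, 0.01)))    # only 1 of 3
  expect_true(pres1(c(0.02, 0.02, 0.0)))      # boundary inclusive

  # exhaustive grid against a direct count, all quorums
  grid <- seq(0, 0.04, 0.005)
  for (q in 1:3) {
    for (a in grid) for (b in grid) for (d in grid) {
      props <- lapply(c(a, b, d), function(x) matrix(x, 1, 1))
      expect_identical(
        unname(note_topic_presence(st, props, quorum = q)[1, 1]),
        sum(c(a, b, d) >= 0.02) >= q
      )
    }
  }
})

test_that("presence is monotone in the proportions", {
  st <- tibble::tibble(stable_id = 1L, run1 = 1L, run2 = 1L, run3 = 1L,
                       min_pairwise_cosine = 1)
  class(st) <- c("stable_topics", class(st))
  withr::with_seed(11, {
    for (r in 1:50) {
      p <- runif(3, 0, 0.05)
      bump <- runif(3, 0, 0.02)
      before <- note_topic_presence(st, lapply(p, matrix, 1, 1))[1, 1]
      after <- note_topic_presence(st, lapply(p + bump, matrix, 1, 1))[1, 1]
      expect_true(after >= before)
    }
  })
})

test_that("subject presence is the OR over the subject's notes", {
  pres <- matrix(c(TRUE, rep(FALSE, 49),
                   rep(FALSE, 50)), ncol = 2,
                 dimnames = list(NULL, c("topic_1", "topic_2")))
  meta <- tibble::tibble(doc_id = 1:50, subject_id = rep("s1", 50),
                         note_date = as.Date("2015-01-01") + 1:50)
  out <- subject_topic_presence(pres, meta)
  expect_equal(out$topic_1, 1L)  # 1 present note among 50
  expect_equal(out$topic_2, 0L)  # 0 present notes

  # random matrix equals a brute-force per-note scan
  withr::with_seed(12, {
    pres2 <- matrix(runif(200) < 0.1, 50, 4,
                    dimnames = list(NULL, paste0("topic_", 1:4)))
    meta2 <- tibble::tibble(doc_id = 1:50,
                            subject_id = sample(c("a", "b", "c"), 50, TRUE),
                            note_date = as.Date("2015-01-01") + 1:50)
  })
  out2 <- subject_topic_presence(pres2, meta2)
  for (s in out2$subject_id) {
    rows <- meta2$subject_id == s
    expect_equal(unlist(out2[out2$subject_id == s, -1]),
                 (colSums(pres2[rows, , drop = FALSE]) > 0) + 0L,
                 ignore_attr = TRUE)
  }

  # a subject with zero notes gets an all-zero row and a warning
  expect_warning(
    out3 <- subject_topic_presence(pres2, meta2,
                                   subject_ids = c("a", "b", "c", "zzz")),
    "no notes")
  expect_equal(sum(unlist(out3[out3$subject_id == "zzz", -1])), 0)
})
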