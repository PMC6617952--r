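# Independent oracles used across tests. These deliberately use brute-force
# or closed-form routes different from the package implementation.

# AUC by exhaustive pair counting over binned counts: concordant pairs
# (positive in a strictly higher bin than a negative) count 1, within-bin
# positive/negative pairs count 1/2.
pair_count_auc <- function(n, u) {
  stopifnot(length(n) == length(u), all(u <= n))
  B <- length(n)
  neg <- n - u
  num <- 0
  for (i in seq_len(B)) {
    if (i < B) num <- num + neg[i] * sum(u[(i + 1):B])
    num <- num + 0.5 * u[i] * neg[i]
  }
  num / (sum(u) * sum(neg))
}

# Sensitivity/specificity at boundary i by direct evaluation of the printed
# summation formulas.
sen_spe_direct <- function(n, u, i) {
  B <- length(n)
  sen <- if (i >= B) 0 else sum(u[(i + 1):B]) / sum(u)
  spe <- if (i == 0) 0 else (sum(n[1:i]) - sum(u[1:i])) / (sum(n) - sum(u))
  c(sen = sen, spe = spe)
}

# Brute-force stable-triple search: over all (i, j, k) triples, greedily take
# the triple with the highest minimum pairwise cosine, remove its topics, and
# repeat while the best min-cosine reaches the threshold.
brute_force_triples <- function(m1, m2, m3, threshold) {
  cos_rows <- function(A, B) {
    (A %*% t(B)) / outer(sqrt(rowSums(A^2)), sqrt(rowSums(B^2)))
  }
  s12 <- cos_rows(m1, m2); s13 <- cos_rows(m1, m3); s23 <- cos_rows(m2, m3)
  K <- nrow(m1)
  avail1 <- avail2 <- avail3 <- rep(TRUE, K)
  out <- list()
  repeat {
    best <- NULL; best_val <- -Inf
    for (i in which(avail1)) for (j in which(avail2)) for (k in which(avail3)) {
      v <- min(s12[i, j], s13[i, k], s23[j, k])
      if (v > best_val) { best_val <- v; best <- c(i, j, k) }
    }
    if (is.null(best) || best_val < threshold) break
    out[[length(out) + 1]] <- best
    avail1[best[1]] <- avail2[best[2]] <- avail3[best[3]] <- FALSE
  }
  if (length(out) == 0) matrix(integer(), 0, 3) else do.call(rbind, out)
}

# Small separable corpus: two groups of documents over disjoint vocabularies.
make_separable_notes <- function(n_per_group = 40, words_per_doc = 25,
                                 seed = 1) {
  vocab_a <- sprintf("alpha%02d", 1:20)
  vocab_b <- sprintf("beta%02d", 1:20)
  withr::with_seed(seed, {
    texts <- c(
      replicate(n_per_group,
                paste(sample(vocab_a, words_per_doc, TRUE), collapse = " ")),
      replicate(n_per_group,
                paste(sample(vocab_b, words_per_doc, TRUE), collapse = " "))
    )
  })
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_along(texts)),
    note_date = as.Date("2015-01-01") + seq_along(texts),
    note_type = "NOTE",
    text = texts
  )
}

# Tiny end-to-end fixture shared by pipeline tests.
tiny_pipeline_config <- function(seed = 7) {
  pipeline_config(
    seed = seed, n_cases = 20, control_ratio = 5,
    n_topics_truth = 6, vocab_size = 150, n_dementia_topics = 2,
    notes_per_day_rate = 0.012, note_length = 40,
    n_topics = 6, lda_iterations = 60,
    infer_iterations = 30, infer_burnin = 10
  )
}
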