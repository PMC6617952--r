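test_that("rank binning hits the target bin count with near-equal sizes", {
  withr::with_seed(61, {
    s <- runif(950, 0.001, 0.999)
  })
  p <- partition_controls(s, target_size = 100)
  expect_equal(nrow(p), 10)
  expect_equal(p$n, rep(95L, 10))
  expect_equal(sum(p$n), 950)
  # boundaries verified against a direct rank computation
  ss <- sort(s)
  expected <- (ss[seq(95, 855, 95)] + ss[seq(96, 856, 95)]) / 2
  expect_equal(attr(p, "boundaries"), c(0, expected, 1))
  expect_true(all(diff(attr(p, "boundaries")) > 0))
  expect_equal(p$midpoint, (p$x_lo + p$x_hi) / 2)

  # a single bin covers [0, 1]
  expect_warning(p1 <- partition_controls(runif(100, 0.1, 0.9), 100),
                 "coarse")
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$x_lo, p1$x_hi), c(0, 1))

  # sizes never differ by more than one
  withr::with_seed(62, {
    p2 <- partition_controls(runif(1037, 0.01, 0.99), 100)
  })
  expect_lte(diff(range(p2$n)), 1)
  expect_equal(sum(p2$n), 1037)
})

test_that("per-bin undiagnosed counts follow the rounded linear rule", {
  mk <- function(n, mid) {
    tbl <- tibble::tibble(bin = seq_along(n), n = as.integer(n),
                          x_lo = mid - 0.05, x_hi = mid + 0.05,
                          midpoint = mid)
    structure(tbl, boundaries = c(0, mid[-1] - 0.05, 1),
              class = c("fine_bins", class(tbl)))
  }
  expect_equal(estimate_undiagnosed(mk(100, 0.5), 0.7)$u, 35L)
  expect_equal(estimate_undiagnosed(mk(c(80, 90), c(0.2, 0.6)), 0)$u,
               c(0L, 0L))
  # 0.5 * 0.05 * 100 = 2.5 rounds up under half-away-from-zero
  expect_equal(estimate_undiagnosed(mk(100, 0.05), 0.5)$u, 3L)
  # a bin can never hold more undiagnosed subjects than subjects
  withr::with_seed(64, {
    for (r in 1:20) {
      n <- sample(1:120, 4)
      mids <- sort(runif(4, 0.01, 0.99))
      u <- estimate_undiagnosed(mk(n, mids), runif(1))$u
      expect_true(all(u <= n & u >= 0))
    }
  })
  expect_error(estimate_undiagnosed(mk(10, 0.5), 1.2), "must be a single")
})

fine_bins_fixture <- function(n, u, boundaries = NULL) {
  B <- length(n)
  if (is.null(boundaries)) boundaries <- seq(0, 1, length.out = B + 1)
  tbl <- tibble::tibble(bin = seq_len(B), n = as.integer(n),
                        x_lo = boundaries[-(B + 1)], x_hi = boundaries[-1],
                        midpoint = (boundaries[-(B + 1)] + boundaries[-1]) / 2,
                        u = as.integer(u))
  structure(tbl, boundaries = boundaries,
            class = c("fine_bins", class(tbl)))
}

test_that("sensitivity and specificity match the summation formulas", {
  p <- fine_bins_fixture(c(10, 10, 10), c(1, 2, 3))
  expect_equal(sen_spe(p, 0)[, c("sen", "spe")],
               tibble::tibble(sen = 1, spe = 0))
  expect_equal(sen_spe(p, 3)[, c("sen", "spe")],
               tibble::tibble(sen = 0, spe = 1))
  at1 <- sen_spe(p, 1)
  expect_equal(at1$sen, 5 / 6)
  expect_equal(at1$spe, 9 / 24)

  expect_error(sen_spe(fine_bins_fixture(c(5, 5), c(0, 0)), 1), "undefined")
  expect_error(sen_spe(p, 4), "0..B")
})

test_that("the ROC curve and trapezoidal AUC behave on canonical cases", {
  # proportional undiagnosed counts put every point on the diagonal
  p_diag <- fine_bins_fixture(c(10, 20, 10, 40), c(1, 2, 1, 4))
  r <- roc_curve(p_diag)
  expect_equal(unname(r$sen), unname(1 - r$spe), tolerance = 1e-12)
  expect_equal(attr(r, "auc"), 0.5, tolerance = 1e-12)

  # the worked 3-bin system
  p3 <- fine_bins_fixture(c(10, 10, 10), c(1, 2, 3))
  r3 <- roc_curve(p3)
  expect_equal(attr(r3, "auc"), 92 / 144, tolerance = 1e-12)

  # all undiagnosed mass in the top bin approaches a perfect classifier
  p_top <- fine_bins_fixture(rep(100, 10), c(rep(0, 9), 50))
  expect_gte(attr(roc_curve(p_top), "auc"), 0.95)
  p_top2 <- fine_bins_fixture(rep(100, 20), c(rep(0, 19), 50))
  expect_gt(attr(roc_curve(p_top2), "auc"), attr(roc_curve(p_top), "auc"))

  # monotonicity of the curve in the boundary index
  expect_true(all(diff(r3$sen) <= 0))
  expect_true(all(diff(r3$spe) >= 0))
})

test_that("trapezoidal AUC equals exhaustive pair counting on random bin systems", {
  withr::with_seed(63, {
    for (rep in 1:50) {
      B <- sample(3:6, 1)
      n <- sample(5:30, B, TRUE)
      u <- vapply(n, function(m) sample(0:m, 1), integer(1))
      if (sum(u) == 0 || sum(u) == sum(n)) next
      p <- fine_bins_fixture(n, u)
      expect_equal(attr(roc_curve(p), "auc"), pair_count_auc(n, u),
                   tolerance = 1e-12)
      i <- sample(0:B, 1)
      expect_equal(unlist(sen_spe(p, i)[, c("sen", "spe")]),
                   sen_spe_direct(n, u, i), ignore_attr = TRUE)
    }
  })
})

test_that("threshold picking matches an exhaustive scan", {
  p3 <- fine_bins_fixture(c(10, 10, 10), c(1, 2, 3))
  r3 <- roc_curve(p3)
  th <- pick_thresholds(r3, sen_target = 0.8, spe_target = 0.8)
  # balanced: exhaustive scan over boundary indices
  gap <- abs(r3$sen - r3$spe)
  expect_equal(th$theta[th$mode == "balanced"],
               r3$theta[which.min(gap)])
  expect_equal(th$theta[th$mode == "high_sensitivity"],
               r3$theta[which.min(abs(r3$sen - 0.8))])
  expect_equal(th$theta[th$mode == "high_specificity"],
               r3$theta[which.min(abs(r3$spe - 0.8))])

  # a symmetric curve has an exactly balanced point
  p_sym <- fine_bins_fixture(c(10, 10), c(2, 8))
  r_sym <- roc_curve(p_sym)
  th_sym <- pick_thresholds(r_sym)
  bal <- th_sym[th_sym$mode == "balanced", ]
  expect_equal(bal$sen, bal$spe)
})

test_that("empirical AUC is the normalised rank sum", {
  score <- c(0.1, 0.4, 0.35, 0.8)
  truth <- c(FALSE, TRUE, FALSE, TRUE)
  # pairs: (0.4 vs 0.1, 0.4 vs 0.35, 0.8 vs 0.1, 0.8 vs 0.35) all concordant
  expect_equal(empirical_auc(score, truth), 1)
  expect_equal(empirical_auc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE)),
               0.25)
})
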