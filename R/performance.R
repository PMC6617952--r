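#' Partition control scores into fine rank-based bins
#'
#' Controls are sorted by risk score and cut into `B = round(N/target_size)`
#' consecutive rank bins whose sizes differ by at most one (larger bins
#' first). Interior boundaries are the mean of the last score in one bin and
#' the first score of the next; the outer boundaries are pinned at 0 and 1.
#' Tied scores keep their stable sort order, so ties at a boundary stay in
#' the lower bin. With ~100 controls per bin the per-bin expected
#' undiagnosed counts from the rate line are stable while thresholds remain
#' fine-grained.
#'
#' @param scores Numeric vector of control risk scores in (0, 1).
#' @param target_size Target controls per bin (default 100).
#' @return A `fine_bins` object: tibble with `bin`, `n`, `x_lo`, `x_hi`,
#'   `midpoint`; the full boundary vector `x_0 ... x_B` is in
#'   `attr(, "boundaries")`.
#' @export
partition_controls <- function(scores, target_size = 100) {
  stopifnot(is.numeric(scores), length(scores) > 0)
  if (any(scores <= 0 | scores >= 1)) {
    stop("scores must lie strictly inside (0, 1)", call. = FALSE)
  }
  target_size <- check_count(target_size, "target_size")
  n <- length(scores)
  B <- max(1L, as.integer(round_half_away(n / target_size)))
  if (n < 2 * target_size) {
    warning("fewer than two bins' worth of scores: partition may be coarse",
            call. = FALSE)
  }
  s <- sort(scores)  # stable
  sizes <- rep(n %/% B, B)
  extra <- n %% B
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  boundaries <- c(0, if (B > 1) (s[ends[-B]] + s[starts[-1]]) / 2, 1)
  tbl <- tibble::tibble(
    bin = seq_len(B), n = as.integer(sizes),
    x_lo = boundaries[-length(boundaries)], x_hi = boundaries[-1],
    midpoint = (boundaries[-length(boundaries)] + boundaries[-1]) / 2
  )
  structure(tbl, boundaries = boundaries, class = c("fine_bins", class(tbl)))
}

#' Estimate per-bin undiagnosed counts from the rate line
#'
#' Applies the zero-intercept rate line to each fine bin:
#' `u_i = round(b * midpoint_i * N_i)`, with ties rounded half away from
#' zero and counts clamped at the bin size (with a warning) since a bin
#' cannot contain more undiagnosed subjects than subjects.
#'
#' @param partition A `fine_bins` object.
#' @param b Zero-intercept slope of the rate line, in `[0, 1]`.
#' @return The partition tibble with an integer `u` column added.
#' @export
estimate_undiagnosed <- function(partition, b) {
  stopifnot(inherits(partition, "fine_bins"))
  check_prob(b, "b")
  u <- as.integer(round_half_away(b * partition$midpoint * partition$n))
  if (any(u > partition$n)) {
    warning("estimated undiagnosed count exceeded bin size; clamped",
            call. = FALSE)
    u <- pmin(u, partition$n)
  }
  out <- dplyr::mutate(partition, u = u)
  attr(out, "boundaries") <- attr(partition, "boundaries")
  class(out) <- class(partition)
  out
}

#' Sensitivity and specificity at a dividing threshold
#'
#' With estimated undiagnosed counts `u_i` in bins of size `N_i`, the
#' sensitivity and specificity of flagging controls above the i-th dividing
#' boundary are
#' `SEN = sum(u[k > i]) / sum(u)` and
#' `SPE = (sum(N[k <= i]) - sum(u[k <= i])) / (sum(N) - sum(u))`.
#' At `i = 0` (flag everyone) SEN = 1 and SPE = 0; at `i = B` (flag no one)
#' SEN = 0 and SPE = 1. When every `u_i` is zero sensitivity is undefined
#' and an error is raised.
#'
#' @param partition A `fine_bins` tibble with a `u` column
#'   (see [estimate_undiagnosed()]).
#' @param i Boundary index, `0 <= i <= B`.
#' @return A tibble: `i`, `theta` (the boundary score), `sen`, `spe`.
#' @export
sen_spe <- function(partition, i) {
  stopifnot(inherits(partition, "fine_bins"), "u" %in% names(partition))
  B <- nrow(partition)
  if (any(i < 0 | i > B)) stop("`i` must lie in 0..B", call. = FALSE)
  U <- sum(partition$u)
  if (U == 0) stop("all estimated undiagnosed counts are zero; sensitivity is undefined",
                   call. = FALSE)
  N <- sum(partition$n)
  boundaries <- attr(partition, "boundaries")
  cu <- c(0, cumsum(partition$u))
  cn <- c(0, cumsum(partition$n))
  tibble::tibble(
    i = i,
    theta = boundaries[i + 1],
    sen = (U - cu[i + 1]) / U,
    spe = (cn[i + 1] - cu[i + 1]) / (N - U)
  )
}

#' ROC curve over all dividing thresholds
#'
#' Evaluates sensitivity and specificity at every boundary `x_0 ... x_B` and
#' computes the area under the curve by the trapezoid rule over
#' `(1 - SPE, SEN)`. For per-bin counts this equals the
#' probability-of-correct-ranking form (cross-bin concordant pairs plus half
#' of the within-bin ties).
#'
#' @param partition A `fine_bins` tibble with `u` (see
#'   [estimate_undiagnosed()]).
#' @return A `silverphen_roc` tibble (`i`, `theta`, `sen`, `spe`) with the
#'   AUC in `attr(, "auc")`.
#' @export
roc_curve <- function(partition) {
  B <- nrow(partition)
  pts <- sen_spe(partition, 0:B)
  fpr <- 1 - pts$spe
  ord <- order(fpr, pts$sen)
  auc <- sum(diff(fpr[ord]) *
               (head(pts$sen[ord], -1) + pts$sen[ord][-1]) / 2)
  structure(pts, auc = auc, class = c("silverphen_roc", class(pts)))
}

#' @export
print.silverphen_roc <- function(x, ...) {
  cat(sprintf("<silverphen_roc> %d thresholds, AUC = %.3f\n",
              nrow(x), attr(x, "auc")))
  NextMethod()
}

#' Pick named operating thresholds from an ROC curve
#'
#' Reports three operating modes: `balanced` (the threshold minimising
#' `|SEN - SPE|`), `high_sensitivity` (the threshold whose sensitivity is
#' closest to `sen_target`) and `high_specificity` (closest specificity to
#' `spe_target`). Ties are broken toward the lower threshold.
#'
#' @param curve A `silverphen_roc` from [roc_curve()].
#' @param sen_target Sensitivity floor for the high-sensitivity mode.
#' @param spe_target Specificity floor for the high-specificity mode.
#' @return A tibble: `mode`, `theta`, `sen`, `spe`.
#' @export
pick_thresholds <- function(curve, sen_target = 0.9, spe_target = 0.9) {
  stopifnot(inherits(curve, "silverphen_roc"))
  pick <- function(obj) {
    # which.min on the objective; ties already resolve to the first (lower
    # threshold) because the curve is ordered by boundary index
    idx <- which.min(obj)
    curve[idx, c("theta", "sen", "spe")]
  }
  dplyr::bind_rows(
    dplyr::mutate(pick(abs(curve$sen - sen_target)),
                  mode = "high_sensitivity", .before = 1),
    dplyr::mutate(pick(abs(curve$sen - curve$spe)), mode = "balanced",
                  .before = 1),
    dplyr::mutate(pick(abs(curve$spe - spe_target)),
                  mode = "high_specificity", .before = 1)
  )
}

#' Empirical AUC of a score against binary truth
#'
#' Rank-based (Mann-Whitney) AUC with ties counted half, used to evaluate
#' scores against planted ground truth in synthetic runs.
#'
#' @param score Numeric score vector.
#' @param truth Logical (or 0/1) vector, same length.
#' @return A single number in `[0, 1]`.
#' @export
empirical_auc <- function(score, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score) == length(truth), any(truth), any(!truth))
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
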