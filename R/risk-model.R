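#' Fit the silver-standard logistic risk model
#'
#' Fits a logistic regression of coded diagnosis status (case = 1,
#' control = 0) on the selected binary features by iteratively reweighted
#' least squares with a light ridge penalty on the coefficients (never the
#' intercept). The penalty guarantees a finite maximum even under complete
#' separation, which is routine with many binary features; at the default
#' `lambda = 1e-6` it is numerically negligible on non-separated data and it
#' can be set to 0 to recover plain maximum likelihood.
#'
#' @param features Feature tibble (`subject_id` + 0/1 columns), typically
#'   restricted to selected features.
#' @param cohort Cohort tibble with `subject_id` and `group`.
#' @param lambda Ridge penalty on coefficients (default 1e-6).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Relative deviance-change convergence tolerance (the usual
#'   GLM criterion), robust under near-separation where coefficient steps
#'   plateau without the fit changing.
#' @return A `risk_model` object with `intercept`, `coefficients` (named),
#'   `lambda`, `converged`, `iterations`, `deviance`, `n`.
#' @export
fit_risk_model <- function(features, cohort, lambda = 1e-6,
                           max_iter = 100, tol = 1e-8) {
  y <- cohort$group[match(features$subject_id, cohort$subject_id)] == "case"
  if (anyNA(y)) stop("features reference subjects absent from the cohort",
                     call. = FALSE)
  if (all(y) || all(!y)) {
    stop("both cases and controls are required to fit the risk model",
         call. = FALSE)
  }
  if (sum(y) < 2 || sum(!y) < 2) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(features[, setdiff(names(features), "subject_id")]))
  storage.mode(X) <- "double"
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)

  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  penalised_dev <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -2 * sum(ifelse(y, log(mu), log(1 - mu))) + sum(b^2 * diag(pen))
  }
  dev_old <- penalised_dev(beta)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X + pen, XtW %*% z))
    dev_new <- penalised_dev(beta)
    rel <- abs(dev_new - dev_old) / (abs(dev_new) + 0.1)
    dev_old <- dev_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(paste0("risk model did not converge in %d IRLS iterations ",
                        "(last relative deviance change %.3g); consider a ",
                        "larger `lambda`"), max_iter, rel), call. = FALSE)
  }
  mu <- pmin(pmax(stats::plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
  dev <- -2 * sum(ifelse(y, log(mu), log(1 - mu)))
  structure(
    list(intercept = beta[1], coefficients = setNames(beta[-1],
                                                      colnames(X)[-1]),
         lambda = lambda, converged = converged, iterations = it,
         deviance = dev, n = length(y)),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d features, n = %d, deviance %.1f (%d IRLS iterations)\n",
              length(x$coefficients), x$n, x$deviance, x$iterations))
  invisible(x)
}

#' @rdname fit_risk_model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname fit_risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$coefficients),
                 deviance = x$deviance, iterations = x$iterations,
                 converged = x$converged, lambda = x$lambda)
}

#' Score subjects with a fitted risk model
#'
#' The risk score is the inverse-logit of the linear predictor, strictly
#' inside (0, 1) and monotone in it. Scores are also assigned to the ten
#' coarse risk bins used for stratified review: bin b covers
#' `[(b-1)/10, b/10)`, with the top bin closed at 1.
#'
#' @param features Feature tibble with the model's feature columns.
#' @param model A `risk_model`.
#' @param cohort Optional cohort tibble; when given, `group` is carried
#'   through.
#' @return A tibble: `subject_id`, (`group`,) `score`, `coarse_bin`.
#' @export
predict_risk_scores <- function(features, model, cohort = NULL) {
  stopifnot(inherits(model, "risk_model"))
  need <- names(model$coefficients)
  missing <- setdiff(need, names(features))
  if (length(missing) > 0) {
    stop(sprintf("features are missing %d model column(s), e.g. %s",
                 length(missing), missing[1]), call. = FALSE)
  }
  X <- as.matrix(features[, need, drop = FALSE])
  score <- stats::plogis(model$intercept + drop(X %*% model$coefficients))
  out <- tibble::tibble(subject_id = features$subject_id, score = score,
                        coarse_bin = coarse_bin(score))
  if (!is.null(cohort)) {
    out <- dplyr::mutate(
      out, group = cohort$group[match(.data$subject_id, cohort$subject_id)],
      .after = "subject_id")
  }
  out
}

#' Coarse risk bins
#'
#' Maps scores in `[0, 1]` to bins 1..10: bin b is `[(b-1)/10, b/10)`, the
#' top bin `[0.9, 1]` closed.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @return Integer bin vector.
#' @export
coarse_bin <- function(score) {
  stopifnot(all(score >= 0 & score <= 1))
  pmin(floor(score * 10) + 1L, 10L)
}

#' Flag probable undiagnosed dementia among controls
#'
#' Controls with risk scores strictly greater than the threshold `theta` are
#' flagged.
#'
#' @param scores Score tibble from [predict_risk_scores()] (controls only or
#'   with a `group` column).
#' @param theta Threshold in `[0, 1]`.
#' @return The flagged rows of `scores`.
#' @export
flag_undiagnosed <- function(scores, theta) {
  check_prob(theta, "theta")
  out <- scores
  if ("group" %in% names(out)) {
    out <- dplyr::filter(out, .data$group == "control")
  }
  dplyr::filter(out, .data$score > theta)
}
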