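# Post-hoc inference on a fitted MDR model: permutation test of the
# reported prediction accuracy, a likelihood-ratio permutation test of
# interaction, and prospective adjustment of the retrospective accuracy
# estimate from a user-supplied population prevalence.

#' Permutation test of MDR prediction accuracy
#'
#' Re-runs the complete fitting pipeline (same scheme, interaction levels
#' and options, fresh internal splits) on `B` datasets whose case-control
#' status has been randomly permuted, and compares the resulting
#' final-model accuracies to a reference accuracy.  The p-value uses the
#' add-one convention `(1 + #(null >= reference)) / (B + 1)` and can never
#' be zero.
#'
#' @param data the [mdr_data] the fit was obtained from.
#' @param fit an `mdr_fit` from [mdr_cv()] or [mdr_3ws()]; its option echo
#'   drives the permuted refits.
#' @param B number of permutations.
#' @param reference accuracy (percent scale) to test; defaults to the
#'   fit's own final prediction (CV) or validation (3WS) accuracy.
#' @param seed optional master seed; per-replicate seeds are derived from
#'   it so the whole test is reproducible.
#' @return An object of class `mdr_permutation` with the observed
#'   statistic, the `B` null statistics and the p-value.
#' @export
permute_fit <- function(data, fit, B = 100, reference = NULL, seed = NULL) {
  stopifnot(inherits(data, "mdr_data"), inherits(fit, "mdr_fit"))
  B <- as.integer(B)
  if (B < 1L) stop("'B' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, B)
  observed <- 100 * .final_accuracy(fit)
  if (is.null(reference)) reference <- observed
  null_stats <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    perm <- data
    perm$status <- sample(data$status)
    perm$n_cases <- data$n_cases
    perm$n_controls <- data$n_controls
    null_stats[b] <- 100 * .final_accuracy(.refit(perm, fit$options))
  }
  p <- (1 + sum(null_stats >= reference - 1e-12)) / (B + 1)
  structure(list(statistic = "prediction accuracy (%)",
                 observed = observed, reference = reference,
                 null_stats = null_stats, p_value = p, B = B, seed = seed),
            class = "mdr_permutation")
}

# Final reported accuracy of a fit on the [0,1] scale.
.final_accuracy <- function(fit) {
  if (fit$scheme == "cv") fit$table$prediction[fit$final_level]
  else fit$table$validation[fit$final_level]
}

# Re-run the pipeline described by an option echo (fresh internal splits
# from the current RNG state).
.refit <- function(data, opt) {
  if (opt$scheme == "cv")
    mdr_cv(data, K = opt$K, cv = opt$cv, ratio = opt$ratio, equal = opt$equal)
  else
    mdr_3ws(data, K = opt$K, x = opt$x, proportion = opt$proportion,
            ratio = opt$ratio, equal = opt$equal)
}

#' @export
print.mdr_permutation <- function(x, ...) {
  cat("Permutation test of", x$statistic, "\n")
  cat(sprintf("  observed: %.3f   reference: %.3f   B = %d\n",
              x$observed, x$reference, x$B))
  cat(sprintf("  p-value: %.4g\n", x$p_value))
  if (!is.null(x$flagged) && x$flagged > 0L)
    cat("  replicates flagged for separation:", x$flagged, "\n")
  invisible(x)
}

#' Likelihood-ratio permutation test of interaction
#'
#' Tests whether the MDR high/low-risk factor for a fixed locus
#' combination explains case-control status beyond the loci's main
#' effects.  The observed statistic is the deviance difference between a
#' logistic regression on the loci as categorical factors and the same
#' model plus the MDR risk factor.  The null distribution is built by
#' permuting status, re-deriving the risk factor on the permuted data for
#' the same loci, and recomputing the deviance difference.  Logistic fits
#' carry a small ridge penalty so that separated tables still yield a
#' finite, comparable deviance; replicates where separation occurred are
#' counted and reported.
#'
#' @param data an [mdr_data] object.
#' @param loci locus combination to test (indices).
#' @param B number of permutations.
#' @param ratio,equal high/low-risk attribution options (see
#'   [attribute_risk()]).
#' @param seed optional seed.
#' @return An `mdr_permutation` object with statistic `"LRT"` and a
#'   `flagged` count of separation-affected replicates.
#' @export
permute_interaction <- function(data, loci, B = 100, ratio = NULL,
                                equal = c("HR", "LR"), seed = NULL) {
  stopifnot(inherits(data, "mdr_data"))
  equal <- match.arg(equal)
  B <- as.integer(B)
  if (B < 1L) stop("'B' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- .interaction_lrt(data$code, data$status, loci, data$levels,
                          ratio, equal)
  null_stats <- numeric(B)
  flagged <- as.integer(obs$separated)
  for (b in seq_len(B)) {
    st <- sample(data$status)
    r <- .interaction_lrt(data$code, st, loci, data$levels, ratio, equal)
    null_stats[b] <- r$lrt
    flagged <- flagged + r$separated
  }
  p <- (1 + sum(null_stats >= obs$lrt - 1e-12)) / (B + 1)
  structure(list(statistic = "LRT (interaction deviance)",
                 observed = obs$lrt, reference = obs$lrt,
                 null_stats = null_stats, p_value = p, B = B, seed = seed,
                 flagged = flagged, loci = as.integer(loci)),
            class = "mdr_permutation")
}

# Deviance difference between main-effects logistic model and main effects
# plus the MDR risk factor, for one status vector.
.interaction_lrt <- function(code, status, loci, levels, ratio, equal) {
  L <- length(levels)
  key <- .combo_key(code, loci, L)
  keep <- !is.na(key)
  key <- key[keep]
  y <- status[keep]
  ck <- code[keep, loci, drop = FALSE]
  fit <- .fit_cells(ck[y == 1L, , drop = FALSE], ck[y == 0L, , drop = FALSE],
                    seq_along(loci), L, ratio, equal)
  risk <- as.numeric(fit$high[key])
  fac <- lapply(seq_along(loci), function(j) factor(ck[, j]))
  X0 <- stats::model.matrix(~ ., data = as.data.frame(fac))
  f0 <- .ridge_logit(X0, y)
  if (length(unique(risk)) < 2L)    # constant risk factor: nested models identical
    return(list(lrt = 0, separated = f0$separated))
  X1 <- cbind(X0, risk = risk)
  f1 <- .ridge_logit(X1, y)
  list(lrt = max(f0$deviance - f1$deviance, 0),
       separated = f0$separated || f1$separated)
}

# Ridge-penalized logistic regression by IRLS.  The penalty (off the
# intercept) keeps the solve well-posed under separation; the returned
# deviance is the unpenalized binomial deviance at the fitted
# probabilities, clamped away from 0/1.
.ridge_logit <- function(X, y, lambda = 1e-6, maxit = 100L, tol = 1e-10) {
  pp <- ncol(X)
  pen <- diag(rep(lambda, pp))
  pen[1L, 1L] <- 0
  beta <- numeric(pp)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-10)
    z <- eta + (y - pr) / w
    XtW <- t(X * w)
    newbeta <- tryCatch(
      drop(solve(XtW %*% X + pen, XtW %*% z)),
      error = function(e) beta)
    if (max(abs(newbeta - beta)) < tol) { beta <- newbeta; break }
    beta <- newbeta
  }
  pr <- stats::plogis(drop(X %*% beta))
  separated <- any(pr > 1 - 1e-6 | pr < 1e-6)
  prc <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
  list(deviance = -2 * sum(y * log(prc) + (1 - y) * log(1 - prc)),
       separated = separated)
}

#' Algebraic prospective adjustment of classification accuracy
#'
#' Retrospective case-control sampling fixes the case fraction by design,
#' so the in-sample accuracy does not estimate prospective accuracy at the
#' population prevalence.  This adjustment computes sensitivity and
#' specificity of the fixed model on the data and re-weights them:
#' `adjusted accuracy = 100 * (prev * sens + (1 - prev) * spec)`.  At
#' `prev = 0.5` this equals 100 x balanced accuracy exactly.
#'
#' @param data an [mdr_data] object.
#' @param model an `mdr_risk` object or an `mdr_fit` (its final model).
#' @param prev population disease prevalence in (0, 1).
#' @return Object of class `mdr_adjusted` with sensitivity, specificity,
#'   adjusted accuracy and adjusted error (percent scale).
#' @export
mdr_ca_adj <- function(data, model, prev) {
  if (inherits(model, "mdr_fit")) model <- model$final_model
  stopifnot(inherits(model, "mdr_risk"))
  if (!is.numeric(prev) || length(prev) != 1L || prev <= 0 || prev >= 1)
    stop("'prev' must be a single prevalence in (0, 1)")
  cc <- confusion_counts(data$status, classify(model, data, empty = "low"))
  if (cc$TP + cc$FN < 1L || cc$TN + cc$FP < 1L)
    stop("model covers no cases or no controls of the data")
  sens <- cc$TP / (cc$TP + cc$FN)
  spec <- cc$TN / (cc$TN + cc$FP)
  acc <- 100 * (prev * sens + (1 - prev) * spec)
  structure(list(prevalence = prev, sensitivity = sens, specificity = spec,
                 adjusted_accuracy = acc, adjusted_error = 100 - acc,
                 method = "algebraic"),
            class = "mdr_adjusted")
}

#' Bootstrap prospective adjustment of classification error
#'
#' Resamples datasets of the original size in which each individual is a
#' case with probability `prev` (cases drawn with replacement from the
#' case stratum, controls from the control stratum), records the fixed
#' model's classification error on each, and averages over `b` samples.
#' As `b` grows this converges to the algebraic adjustment
#' ([mdr_ca_adj()]).
#'
#' @inheritParams mdr_ca_adj
#' @param b number of bootstrap samples (default 100).
#' @param seed optional seed.
#' @param fixed_cases draw exactly `round(n * prev)` cases per sample
#'   instead of a binomial number (default `FALSE`).
#' @return Object of class `mdr_adjusted` with error/accuracy estimates,
#'   their Monte-Carlo standard error, and `b`.
#' @export
boot_error <- function(data, model, prev, b = 100, seed = NULL,
                       fixed_cases = FALSE) {
  if (inherits(model, "mdr_fit")) model <- model$final_model
  stopifnot(inherits(model, "mdr_risk"))
  if (!is.numeric(prev) || length(prev) != 1L || prev <= 0 || prev >= 1)
    stop("'prev' must be a single prevalence in (0, 1)")
  b <- as.integer(b)
  if (b < 1L) stop("'b' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  pred <- classify(model, data, empty = "low")
  keep <- !is.na(pred)
  wrong <- as.integer(pred[keep] != data$status[keep])
  st <- data$status[keep]
  wrong_ca <- wrong[st == 1L]
  wrong_co <- wrong[st == 0L]
  if (length(wrong_ca) == 0L || length(wrong_co) == 0L)
    stop("both status strata must be scored by the model")
  n <- length(wrong)
  m <- if (fixed_cases) rep.int(round(n * prev), b)
       else stats::rbinom(b, n, prev)
  err <- vapply(m, function(mi) {
    e <- 0L
    if (mi > 0L) e <- e + sum(wrong_ca[sample.int(length(wrong_ca), mi,
                                                  replace = TRUE)])
    if (mi < n) e <- e + sum(wrong_co[sample.int(length(wrong_co), n - mi,
                                                 replace = TRUE)])
    e / n
  }, numeric(1L))
  structure(list(prevalence = prev,
                 error = 100 * mean(err),
                 adjusted_accuracy = 100 * (1 - mean(err)),
                 adjusted_error = 100 * mean(err),
                 se = 100 * stats::sd(err) / sqrt(b),
                 b = b, method = "bootstrap"),
            class = "mdr_adjusted")
}

#' @export
print.mdr_adjusted <- function(x, ...) {
  if (x$method == "bootstrap") {
    cat("$`classification error estimate`\n")
    cat(sprintf("[1] %.3f\n\n", x$adjusted_error))
    cat("$`classification accuracy estimate`\n")
    cat(sprintf("[1] %.3f\n", x$adjusted_accuracy))
  } else {
    cat("$`adjusted classification accuracy`\n")
    cat(sprintf("[1] %.2f\n\n", x$adjusted_accuracy))
    cat("$`adjusted classification error`\n")
    cat(sprintf("[1] %.2f\n", x$adjusted_error))
  }
  invisible(x)
}
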