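# Internal validation: stratified k-fold cross-validation and three-way
# split (training/testing/validation).  Both return an "mdr_fit" carrying a
# per-interaction-level summary table, the selected final model refit on the
# full data, and an echo of the options so post-hoc permutation tests can
# re-run the identical pipeline.

#' Stratified fold assignment for cross-validation
#'
#' Randomly partitions individuals into `k` folds, stratified by case
#' status so that within each stratum fold sizes differ by at most one.
#'
#' @param data an [mdr_data] object.
#' @param k number of folds (2 <= k <= stratum sizes).
#' @param seed optional integer seed for reproducibility.
#' @return Integer vector of fold labels in `1..k`, one per individual.
#' @export
assign_folds <- function(data, k, seed = NULL) {
  stopifnot(inherits(data, "mdr_data"))
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  if (min(data$n_cases, data$n_controls) < k)
    stop("'k' (", k, ") exceeds the size of a status stratum (",
         min(data$n_cases, data$n_controls), ")")
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(data$status))
  for (s in c(1L, 0L)) {
    idx <- which(data$status == s)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified three-way split
#'
#' Splits individuals into disjoint training, testing and validation sets
#' at the given proportions, stratified by case status with
#' largest-remainder rounding inside each stratum.
#'
#' @param data an [mdr_data] object.
#' @param proportion positive weights for train:test:validation
#'   (normalized; default `c(2, 2, 1)`).
#' @param seed optional integer seed.
#' @return List of integer index vectors `train`, `test`, `validation`.
#' @export
split_three_way <- function(data, proportion = c(2, 2, 1), seed = NULL) {
  stopifnot(inherits(data, "mdr_data"))
  if (length(proportion) != 3L || any(proportion <= 0))
    stop("'proportion' must be three positive weights (train:test:validation)")
  w <- proportion / sum(proportion)
  if (!is.null(seed)) set.seed(seed)
  parts <- list(train = integer(0), test = integer(0), validation = integer(0))
  extra_given <- integer(3L)
  for (s in c(1L, 0L)) {
    idx <- sample(which(data$status == s))
    n_s <- length(idx)
    base <- floor(n_s * w)
    rem <- n_s * w - base
    extra <- n_s - sum(base)
    if (extra > 0L) {
      # largest remainder; ties go to the set shortchanged in earlier strata
      pick <- order(-rem, extra_given, seq_len(3L))[seq_len(extra)]
      base[pick] <- base[pick] + 1L
      extra_given[pick] <- extra_given[pick] + 1L
    }
    cuts <- cumsum(base)
    parts$train <- c(parts$train, idx[seq_len(base[1L])])
    parts$test <- c(parts$test, idx[seq_len(base[2L]) + cuts[1L]])
    parts$validation <- c(parts$validation, idx[seq_len(base[3L]) + cuts[2L]])
  }
  if (any(lengths(parts) == 0L))
    stop("a split is empty; use more data or less extreme proportions")
  parts
}

#' MDR with k-fold cross-validation
#'
#' For each interaction level `1..K` and each of the `cv` folds, an
#' exhaustive search on the training folds selects the best locus
#' combination by balanced accuracy, which is then scored on the held-out
#' fold.  Per level, the combination selected in the most folds is reported
#' with its cross-validation consistency (number of folds choosing it), its
#' classification accuracy (training balanced accuracy refit on the full
#' data) and its prediction accuracy (mean held-out balanced accuracy over
#' the folds that chose it).  The final level maximizes prediction
#' accuracy, then consistency, then parsimony; the final model is the
#' winning combination re-attributed on the full dataset.
#'
#' @param data an [mdr_data] object.
#' @param K highest interaction level (combination size) to consider.
#' @param cv number of cross-validation folds (default 5).
#' @param ratio case:control threshold for high-risk attribution; `NULL`
#'   uses the training data's case:control ratio.
#' @param equal tie rule when a cell's ratio equals the threshold.
#' @param seed optional integer seed controlling the fold assignment.
#' @return An object of class `mdr_fit` (scheme `"cv"`).
#' @seealso [summary.mdr_fit()], [plot.mdr_fit()], [predict.mdr_fit()],
#'   [mdr_3ws()]
#' @examples
#' d <- simulate_mdr(mdr1_spec(), seed = 7)
#' fit <- mdr_cv(d, K = 2, cv = 5, seed = 7)
#' summary(fit)
#' @export
mdr_cv <- function(data, K = 2, cv = 5, ratio = NULL, equal = c("HR", "LR"),
                   seed = NULL) {
  stopifnot(inherits(data, "mdr_data"))
  equal <- match.arg(equal)
  K <- as.integer(K)
  p <- ncol(data$code)
  if (K < 1L || K > p) stop("'K' must be between 1 and the number of loci")
  if (!is.null(seed)) set.seed(seed)
  folds <- assign_folds(data, cv)
  L <- length(data$levels)
  gc <- data$code
  st <- data$status

  sel_loci <- vector("list", K)      # [[level]][[fold]] locus tuple
  sel_test <- matrix(NA_real_, nrow = K, ncol = cv)
  for (f in seq_len(cv)) {
    tr <- folds != f
    gtr_ca <- gc[tr & st == 1L, , drop = FALSE]
    gtr_co <- gc[tr & st == 0L, , drop = FALSE]
    gte_ca <- gc[!tr & st == 1L, , drop = FALSE]
    gte_co <- gc[!tr & st == 0L, , drop = FALSE]
    for (lev in seq_len(K)) {
      best <- .search_best(gtr_ca, gtr_co, lev, L, ratio, equal)
      sel_loci[[lev]][[f]] <- best$loci
      sel_test[lev, f] <- .score_ba(gte_ca, gte_co, best$loci, L, best$high)
    }
  }

  gca <- gc[st == 1L, , drop = FALSE]
  gco <- gc[st == 0L, , drop = FALSE]
  win_loci <- vector("list", K)
  class_acc <- pred_acc <- numeric(K)
  cvc <- integer(K)
  for (lev in seq_len(K)) {
    keys <- vapply(sel_loci[[lev]], paste, character(1L), collapse = ",")
    tab <- table(keys)
    cand <- names(tab)[tab == max(tab)]
    # most-selected combination; frequency ties resolve lexicographically
    cand_loci <- lapply(strsplit(cand, ","), as.integer)
    ord <- do.call(order, as.data.frame(do.call(rbind, cand_loci)))
    winner <- cand_loci[[ord[1L]]]
    win_loci[[lev]] <- winner
    hit <- keys == paste(winner, collapse = ",")
    cvc[lev] <- sum(hit)
    pred_acc[lev] <- mean(sel_test[lev, hit], na.rm = TRUE)
    class_acc[lev] <- .fit_cells(gca, gco, winner, L, ratio, equal)$ba
  }

  final_level <- order(-pred_acc, -cvc, seq_len(K))[1L]
  final_fit <- .fit_cells(gca, gco, win_loci[[final_level]], L, ratio, equal)

  structure(list(
    scheme = "cv",
    table = data.frame(
      level = seq_len(K),
      model = vapply(win_loci, function(l)
        paste(data$locus_names[l], collapse = " "), character(1L)),
      loci = I(win_loci),
      classification = class_acc,
      prediction = pred_acc,
      consistency = cvc
    ),
    final_level = final_level,
    final_loci = win_loci[[final_level]],
    final_model = .as_risk(final_fit, win_loci[[final_level]], data,
                           ratio = ratio, equal = equal),
    cells = count_cells(data, win_loci[[final_level]]),
    options = list(scheme = "cv", K = K, cv = as.integer(cv), ratio = ratio,
                   equal = equal, seed = seed),
    levels = data$levels,
    locus_names = data$locus_names,
    n = length(st)
  ), class = "mdr_fit")
}

#' MDR with three-way split internal validation
#'
#' The data are split into training, testing and validation sets.  Per
#' interaction level, the `x` combinations with the highest training
#' balanced accuracy are carried forward; each is re-attributed on the
#' testing set and the testing winner is then scored on the validation set
#' using cells attributed on the pooled training + testing data.  The final
#' level maximizes validation accuracy; the final model is refit on the
#' full dataset.
#'
#' @inheritParams mdr_cv
#' @param x number of top training-set models carried to the testing stage
#'   per level (default 10; clamped to `choose(p, level)` with a warning).
#' @param proportion train:test:validation weights (default `c(2, 2, 1)`).
#' @return An object of class `mdr_fit` (scheme `"3ws"`).
#' @examples
#' d <- simulate_mdr(mdr1_spec(), seed = 7)
#' fit <- mdr_3ws(d, K = 2, seed = 7)
#' summary(fit)
#' @export
mdr_3ws <- function(data, K = 2, x = 10, proportion = c(2, 2, 1),
                    ratio = NULL, equal = c("HR", "LR"), seed = NULL) {
  stopifnot(inherits(data, "mdr_data"))
  equal <- match.arg(equal)
  K <- as.integer(K)
  x <- as.integer(x)
  p <- ncol(data$code)
  if (K < 1L || K > p) stop("'K' must be between 1 and the number of loci")
  if (x < 1L) stop("'x' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  parts <- split_three_way(data, proportion)
  L <- length(data$levels)
  gc <- data$code
  st <- data$status
  stratum <- function(idx, s) gc[idx[st[idx] == s], , drop = FALSE]
  gtr_ca <- stratum(parts$train, 1L); gtr_co <- stratum(parts$train, 0L)
  gte_ca <- stratum(parts$test, 1L);  gte_co <- stratum(parts$test, 0L)
  gva_ca <- stratum(parts$validation, 1L); gva_co <- stratum(parts$validation, 0L)
  ptr <- c(parts$train, parts$test)
  gpool_ca <- gc[ptr[st[ptr] == 1L], , drop = FALSE]
  gpool_co <- gc[ptr[st[ptr] == 0L], , drop = FALSE]

  win_loci <- vector("list", K)
  train_acc <- test_acc <- valid_acc <- numeric(K)
  for (lev in seq_len(K)) {
    x_lev <- x
    if (x_lev > choose(p, lev)) {
      x_lev <- choose(p, lev)
      warning("'x' exceeds the number of level-", lev,
              " combinations; clamped to ", x_lev)
    }
    res <- .search_level(gtr_ca, gtr_co, lev, L, ratio, equal)
    ord <- order(-res$ba)[seq_len(x_lev)]
    test_ba <- vapply(ord, function(i)
      .fit_cells(gte_ca, gte_co, res$combos[, i], L, ratio, equal)$ba,
      numeric(1L))
    best <- ord[which.max(test_ba)]   # ties: higher training rank, then lexicographic
    winner <- res$combos[, best]
    win_loci[[lev]] <- winner
    train_acc[lev] <- res$ba[best]
    test_acc[lev] <- max(test_ba)
    pool <- .fit_cells(gpool_ca, gpool_co, winner, L, ratio, equal)
    valid_acc[lev] <- .score_ba(gva_ca, gva_co, winner, L, pool$high)
  }

  final_level <- order(-valid_acc, seq_len(K))[1L]
  gca <- gc[st == 1L, , drop = FALSE]
  gco <- gc[st == 0L, , drop = FALSE]
  final_fit <- .fit_cells(gca, gco, win_loci[[final_level]], L, ratio, equal)

  structure(list(
    scheme = "3ws",
    table = data.frame(
      level = seq_len(K),
      model = vapply(win_loci, function(l)
        paste(data$locus_names[l], collapse = " "), character(1L)),
      loci = I(win_loci),
      training = train_acc,
      testing = test_acc,
      validation = valid_acc
    ),
    final_level = final_level,
    final_loci = win_loci[[final_level]],
    final_model = .as_risk(final_fit, win_loci[[final_level]], data,
                           ratio = ratio, equal = equal),
    cells = count_cells(data, win_loci[[final_level]]),
    options = list(scheme = "3ws", K = K, x = x, proportion = proportion,
                   ratio = ratio, equal = equal, seed = seed),
    levels = data$levels,
    locus_names = data$locus_names,
    n = length(st)
  ), class = "mdr_fit")
}

#' @export
print.mdr_fit <- function(x, ...) {
  cat("MDR fit (",
      if (x$scheme == "cv") paste0(x$options$cv, "-fold cross-validation")
      else "three-way split validation", ")\n", sep = "")
  cat("Final model: loci", x$table$model[x$final_level],
      "( level", x$final_level, ")\n")
  acc <- if (x$scheme == "cv") x$table$prediction[x$final_level]
         else x$table$validation[x$final_level]
  cat(sprintf("%s accuracy: %.2f%%\n",
              if (x$scheme == "cv") "Prediction" else "Validation", 100 * acc))
  cat("Use summary() for the per-level table.\n")
  invisible(x)
}

#' Predict case-control status on new data
#'
#' Applies the fit's final risk model to an independent dataset.  When the
#' new data carry a status column, a confusion table and balanced accuracy
#' are returned alongside the predicted labels.
#'
#' @param object an `mdr_fit` from [mdr_cv()] or [mdr_3ws()].
#' @param newdata an [mdr_data] object (labels plus accuracy) or a bare
#'   genotype matrix/data frame (labels only).
#' @param empty policy for genotype cells unseen when the final model was
#'   attributed (`"low"` predicts control, `"exclude"` drops).
#' @param ... unused.
#' @return An object of class `mdr_prediction`: predicted labels, and when
#'   truth is available the confusion counts and balanced accuracy.
#' @export
predict.mdr_fit <- function(object, newdata, empty = c("low", "exclude"), ...) {
  empty <- match.arg(empty)
  has_truth <- inherits(newdata, "mdr_data")
  if (!has_truth)
    newdata <- mdr_data(newdata, status = rep.int(0L, NROW(newdata)),
                        levels = object$levels)
  p_fit <- length(object$locus_names)
  if (ncol(newdata$code) != p_fit)
    stop("new data has ", ncol(newdata$code), " loci but the fit used ", p_fit)
  miss <- setdiff(object$final_model$locus_names, newdata$locus_names)
  if (length(miss) > 0L)
    stop("new data is missing model loci: ", paste(miss, collapse = ", "))
  pred <- classify(object$final_model, newdata, empty = empty)
  out <- list(labels = pred, loci = object$final_loci,
              model = object$table$model[object$final_level])
  if (has_truth) {
    cc <- confusion_counts(newdata$status, pred)
    out$confusion <- cc
    out$ba <- if (cc$TP + cc$FN >= 1L && cc$TN + cc$FP >= 1L)
      balanced_accuracy(cc) else NA_real_
  }
  structure(out, class = "mdr_prediction")
}

#' @export
print.mdr_prediction <- function(x, ...) {
  cat("MDR predictions from model", x$model, "\n")
  cat("  predicted cases:", sum(x$labels == 1L, na.rm = TRUE),
      " controls:", sum(x$labels == 0L, na.rm = TRUE),
      " excluded:", sum(is.na(x$labels)), "\n")
  if (!is.null(x$ba))
    cat(sprintf("  balanced accuracy against supplied status: %.2f%%\n",
                100 * x$ba))
  invisible(x)
}
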