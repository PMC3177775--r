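# Core MDR machinery: per-cell case/control tabulation, high/low-risk
# attribution, balanced accuracy and the exhaustive combination search.
#
# A "cell" is one multi-locus genotype combination.  The MDR rule labels a
# cell high-risk when its case:control ratio exceeds a threshold (default:
# the overall case:control ratio of the data used for attribution), then
# classifies individuals by the label of their cell.

#' Tabulate case/control counts per genotype cell
#'
#' Counts cases and controls in every genotype combination of the given
#' loci.  Individuals with a missing genotype at any of the loci are
#' excluded from the table (row-wise, per combination).
#'
#' @param data an [mdr_data] object.
#' @param loci vector of distinct locus (column) indices, length >= 1.
#' @return An object of class `mdr_cells` with per-cell case counts `ca`
#'   and control counts `co` (vectors over all `L^k` cells in key order),
#'   the locus tuple, and the number of individuals used/excluded.
#' @examples
#' d <- mdr_data(matrix(c(0, 0, 1, 1, 0, 0, 1, 1), ncol = 2),
#'               status = c(1, 1, 0, 0))
#' count_cells(d, c(1, 2))
#' @export
count_cells <- function(data, loci) {
  stopifnot(inherits(data, "mdr_data"))
  loci <- as.integer(loci)
  p <- ncol(data$code)
  if (length(loci) < 1L)
    stop("at least one locus is required (k >= 1)")
  bad <- loci < 1L | loci > p
  if (any(bad))
    stop("locus index out of range: ", paste(loci[bad], collapse = ", "))
  if (anyDuplicated(loci))
    stop("duplicate locus index: ", loci[duplicated(loci)][1L])
  L <- length(data$levels)
  ncell <- L^length(loci)
  key <- .combo_key(data$code, loci, L)
  ca <- tabulate(key[data$status == 1L], ncell)
  co <- tabulate(key[data$status == 0L], ncell)
  structure(list(
    loci        = loci,
    levels      = data$levels,
    locus_names = data$locus_names[loci],
    ca          = ca,
    co          = co,
    n_used      = sum(ca) + sum(co),
    n_excluded  = length(key) - sum(!is.na(key))
  ), class = "mdr_cells")
}

#' @export
print.mdr_cells <- function(x, ...) {
  k <- length(x$loci)
  obs <- which(x$ca + x$co > 0L)
  g <- .decode_key(obs, k, length(x$levels))
  tab <- data.frame(matrix(x$levels[g + 1L], ncol = k), x$ca[obs], x$co[obs])
  colnames(tab) <- c(x$locus_names, "cases", "controls")
  cat("Genotype cell counts for loci", paste(x$locus_names, collapse = ", "),
      "(", x$n_used, "individuals used )\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Attribute high/low risk to genotype cells
#'
#' Labels every observed cell HIGH when its case:control ratio exceeds the
#' threshold and LOW when below; a ratio exactly equal to the threshold
#' follows the tie rule (`"HR"`: high-risk, `"LR"`: low-risk).  Cells with
#' cases but no controls are HIGH, controls but no cases LOW, and cells
#' never observed are EMPTY.
#'
#' @param cells an `mdr_cells` table from [count_cells()].
#' @param ratio case:control threshold; `NULL` (default) uses
#'   `n_cases / n_controls` of the tabulated data.
#' @param equal tie rule for cells whose ratio equals the threshold.
#' @param n_cases,n_controls totals defining the automatic threshold;
#'   default to the sums of the cell table.
#' @return An object of class `mdr_risk` carrying the locus tuple, logical
#'   `high` / `observed` vectors over the cells, the realized threshold and
#'   the options used.
#' @export
attribute_risk <- function(cells, ratio = NULL, equal = c("HR", "LR"),
                           n_cases = sum(cells$ca), n_controls = sum(cells$co)) {
  stopifnot(inherits(cells, "mdr_cells"))
  equal <- match.arg(equal)
  if (is.null(ratio)) {
    if (n_cases < 1L || n_controls < 1L)
      stop("automatic threshold needs at least one case and one control")
    d <- cells$ca * n_controls - cells$co * n_cases
    threshold <- n_cases / n_controls
  } else {
    if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
      stop("'ratio' must be a single positive number")
    d <- cells$ca - ratio * cells$co
    threshold <- ratio
  }
  observed <- (cells$ca + cells$co) > 0L
  high <- if (equal == "HR") d >= 0 else d > 0
  high <- high & observed
  structure(list(
    loci        = cells$loci,
    levels      = cells$levels,
    locus_names = cells$locus_names,
    high        = high,
    observed    = observed,
    threshold   = threshold,
    ratio       = ratio,
    equal       = equal
  ), class = "mdr_risk")
}

#' @export
print.mdr_risk <- function(x, ...) {
  k <- length(x$loci)
  obs <- which(x$observed)
  g <- .decode_key(obs, k, length(x$levels))
  tab <- data.frame(matrix(x$levels[g + 1L], ncol = k),
                    ifelse(x$high[obs], "HIGH", "LOW"))
  colnames(tab) <- c(x$locus_names, "risk")
  cat("MDR risk attribution for loci", paste(x$locus_names, collapse = ", "),
      sprintf("(threshold %.4g, ties %s)\n", x$threshold, x$equal))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Classify individuals with a fitted risk model
#'
#' Predicts case status 1 for individuals whose genotype cell is HIGH and 0
#' for LOW.  Individuals in cells never observed during attribution are
#' predicted 0 under the default `empty = "low"` policy, or dropped (`NA`)
#' under `"exclude"`.  Individuals with a missing genotype at any model
#' locus are always excluded (`NA`).
#'
#' @param model an `mdr_risk` object.
#' @param data an [mdr_data] object sharing the model's level set.
#' @param empty policy for cells unseen at attribution time.
#' @return Integer vector of predicted labels (`NA` = excluded).
#' @export
classify <- function(model, data, empty = c("low", "exclude")) {
  stopifnot(inherits(model, "mdr_risk"), inherits(data, "mdr_data"))
  empty <- match.arg(empty)
  if (!identical(data$levels, model$levels))
    stop("genotype level set of the data does not match the model")
  if (max(model$loci) > ncol(data$code))
    stop("data does not cover model loci: ",
         paste(model$loci[model$loci > ncol(data$code)], collapse = ", "))
  key <- .combo_key(data$code, model$loci, length(model$levels))
  pred <- as.integer(model$high[key])
  if (empty == "exclude") pred[!is.na(key) & !model$observed[key]] <- NA
  pred
}

#' Confusion counts from true and predicted labels
#'
#' @param truth vector of true 0/1 labels.
#' @param pred vector of predicted 0/1 labels; `NA` entries (excluded
#'   individuals) are dropped together with their truth.
#' @return List with counts `TP`, `TN`, `FP`, `FN` (class
#'   `mdr_confusion`).
#' @export
confusion_counts <- function(truth, pred) {
  keep <- !is.na(pred) & !is.na(truth)
  truth <- truth[keep]
  pred <- pred[keep]
  structure(list(
    TP = sum(truth == 1L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L)
  ), class = "mdr_confusion")
}

#' Balanced accuracy
#'
#' The arithmetic mean of sensitivity and specificity,
#' `0.5 * (TP/(TP+FN) + TN/(TN+FP))`, on the \[0, 1\] scale.  Robust to
#' case-control imbalance; equals plain classification accuracy when the
#' scored data are balanced.
#'
#' @param x an `mdr_confusion` object, or the `TP` count.
#' @param TN,FP,FN remaining counts when `x` is given as `TP`.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(x, TN = NULL, FP = NULL, FN = NULL) {
  if (inherits(x, "mdr_confusion")) {
    TP <- x$TP; TN <- x$TN; FP <- x$FP; FN <- x$FN
  } else TP <- x
  if (TP + FN < 1L)
    stop("no cases scored: sensitivity undefined")
  if (TN + FP < 1L)
    stop("no controls scored: specificity undefined")
  0.5 * (TP / (TP + FN) + TN / (TN + FP))
}

#' Fit and score one locus combination
#'
#' Runs the full MDR pipeline for a single locus tuple: tabulate cells,
#' attribute high/low risk, classify the same data and compute the training
#' balanced accuracy.
#'
#' @inheritParams count_cells
#' @inheritParams attribute_risk
#' @return List with the `mdr_risk` model, the `mdr_cells` table and the
#'   training balanced accuracy `ba`.
#' @export
evaluate_combination <- function(data, loci, ratio = NULL, equal = c("HR", "LR")) {
  equal <- match.arg(equal)
  cells <- count_cells(data, loci)
  model <- attribute_risk(cells, ratio = ratio, equal = equal)
  ca_tot <- sum(cells$ca)
  co_tot <- sum(cells$co)
  if (ca_tot < 1L || co_tot < 1L)
    stop("balanced accuracy needs at least one scored case and control")
  tp <- sum(cells$ca[model$high])
  tn <- co_tot - sum(cells$co[model$high])
  list(model = model, cells = cells,
       ba = 0.5 * (tp / ca_tot + tn / co_tot))
}

#' Exhaustive search over all k-locus combinations
#'
#' Evaluates every one of the `choose(p, k)` locus combinations by training
#' balanced accuracy and returns them ranked (descending; ties broken by
#' lexicographic locus order, so the result is deterministic).
#'
#' @inheritParams count_cells
#' @inheritParams attribute_risk
#' @param k interaction order (number of loci per combination).
#' @param top return only the first `top` rows (default: all).
#' @return Data frame with list-column `loci`, display string `model` and
#'   training balanced accuracy `ba` (on the \[0, 1\] scale), best first.
#' @examples
#' set.seed(1)
#' d <- mdr_data(matrix(sample(0:2, 60, TRUE), ncol = 3),
#'               status = rep(0:1, each = 10))
#' mdr_search(d, k = 2)
#' @export
mdr_search <- function(data, k, ratio = NULL, equal = c("HR", "LR"), top = NULL) {
  stopifnot(inherits(data, "mdr_data"))
  equal <- match.arg(equal)
  p <- ncol(data$code)
  if (k < 1L || k > p)
    stop("'k' must be between 1 and the number of loci (", p, ")")
  st <- data$status
  res <- .search_level(data$code[st == 1L, , drop = FALSE],
                       data$code[st == 0L, , drop = FALSE],
                       k, length(data$levels), ratio, equal)
  ord <- order(-res$ba)
  if (!is.null(top)) ord <- ord[seq_len(min(top, length(ord)))]
  loci <- lapply(ord, function(i) res$combos[, i])
  data.frame(
    loci  = I(loci),
    model = vapply(loci, function(l)
      paste(data$locus_names[l], collapse = " "), character(1L)),
    ba    = res$ba[ord]
  )
}

# ---- internal fast path ----------------------------------------------------
# The validation schemes evaluate thousands of combinations; these helpers
# work on pre-split case/control code matrices and skip all object building.

# Training balanced accuracy for every k-combination.  Returns the combn
# matrix (lexicographic order) and the BA vector; ties in downstream
# order(-ba) therefore resolve lexicographically.
.search_level <- function(gca, gco, k, L, ratio, equal) {
  p <- ncol(gca)
  combos <- utils::combn(p, k)
  m <- ncol(combos)
  ba <- numeric(m)
  ncell <- L^k
  hr <- equal == "HR"
  for (i in seq_len(m)) {
    loci <- combos[, i]
    kca <- .combo_key(gca, loci, L)
    kco <- .combo_key(gco, loci, L)
    ca <- tabulate(kca, ncell)
    co <- tabulate(kco, ncell)
    ca_tot <- sum(ca)
    co_tot <- sum(co)
    d <- if (is.null(ratio)) ca * co_tot - co * ca_tot else ca - ratio * co
    high <- (if (hr) d >= 0 else d > 0) & (ca + co > 0L)
    tp <- sum(ca[high])
    tn <- co_tot - sum(co[high])
    ba[i] <- 0.5 * (tp / ca_tot + tn / co_tot)
  }
  list(combos = combos, ba = ba)
}

# Best single combination at level k (search + its high-cell vector).
.search_best <- function(gca, gco, k, L, ratio, equal) {
  res <- .search_level(gca, gco, k, L, ratio, equal)
  i <- which.max(res$ba)   # combn order => lexicographic tie-break
  loci <- res$combos[, i]
  fit <- .fit_cells(gca, gco, loci, L, ratio, equal)
  list(loci = loci, ba = fit$ba, high = fit$high, observed = fit$observed)
}

# Attribute one combination on (gca, gco); returns high/observed vectors and
# the training BA.
.fit_cells <- function(gca, gco, loci, L, ratio, equal) {
  ncell <- L^length(loci)
  ca <- tabulate(.combo_key(gca, loci, L), ncell)
  co <- tabulate(.combo_key(gco, loci, L), ncell)
  ca_tot <- sum(ca)
  co_tot <- sum(co)
  d <- if (is.null(ratio)) ca * co_tot - co * ca_tot else ca - ratio * co
  observed <- (ca + co) > 0L
  high <- (if (equal == "HR") d >= 0 else d > 0) & observed
  tp <- sum(ca[high])
  tn <- co_tot - sum(co[high])
  list(high = high, observed = observed, ca = ca, co = co,
       ba = 0.5 * (tp / ca_tot + tn / co_tot),
       threshold = if (is.null(ratio)) ca_tot / co_tot else ratio)
}

# Held-out balanced accuracy: classify (gca, gco) with a fitted high vector;
# unseen/EMPTY cells predict low.  NA when a stratum scores nobody.
.score_ba <- function(gca, gco, loci, L, high) {
  kca <- .combo_key(gca, loci, L)
  kco <- .combo_key(gco, loci, L)
  kca <- kca[!is.na(kca)]
  kco <- kco[!is.na(kco)]
  if (length(kca) == 0L || length(kco) == 0L) return(NA_real_)
  0.5 * (sum(high[kca]) / length(kca) + sum(!high[kco]) / length(kco))
}

# Wrap a .fit_cells result as a user-facing mdr_risk object.
.as_risk <- function(fit, loci, data, ratio = NULL, equal = "HR") {
  structure(list(
    loci        = as.integer(loci),
    levels      = data$levels,
    locus_names = data$locus_names[loci],
    high        = fit$high,
    observed    = fit$observed,
    threshold   = fit$threshold,
    ratio       = ratio,
    equal       = equal
  ), class = "mdr_risk")
}
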