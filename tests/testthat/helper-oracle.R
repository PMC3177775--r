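# Naive reference implementation of the MDR rule, kept deliberately
# independent of the package internals: genotype cells are addressed by
# character keys, counting and classification are explicit per-row loops,
# and risk attribution divides ratios directly.  Used to cross-check cell
# counts, attribution, balanced accuracy, the exhaustive search, and the
# validation pipelines at small scale.

o_counts <- function(geno, status, loci) {
  sub <- geno[, loci, drop = FALSE]
  counts <- list()
  for (i in seq_len(nrow(sub))) {
    if (anyNA(sub[i, ])) next
    k <- paste(sub[i, ], collapse = "|")
    if (is.null(counts[[k]])) counts[[k]] <- c(ca = 0, co = 0)
    if (status[i] == 1) counts[[k]]["ca"] <- counts[[k]]["ca"] + 1
    else counts[[k]]["co"] <- counts[[k]]["co"] + 1
  }
  counts
}

o_risk <- function(counts, threshold = NULL, equal = "HR") {
  ca_tot <- sum(vapply(counts, function(x) x[["ca"]], 0))
  co_tot <- sum(vapply(counts, function(x) x[["co"]], 0))
  if (is.null(threshold)) threshold <- ca_tot / co_tot
  out <- character(0)
  for (k in names(counts)) {
    ca <- counts[[k]][["ca"]]
    co <- counts[[k]][["co"]]
    out[k] <-
      if (co == 0) "HIGH"
      else {
        r <- ca / co
        if (r > threshold) "HIGH"
        else if (r < threshold) "LOW"
        else if (equal == "HR") "HIGH" else "LOW"
      }
  }
  out
}

o_ba <- function(tp, tn, fp, fn) 0.5 * (tp / (tp + fn) + tn / (tn + fp))

# Empty/unseen cells predict low; rows with missing genotype at the loci
# are excluded (NA).
o_classify <- function(risk, geno, loci) {
  sub <- geno[, loci, drop = FALSE]
  pred <- rep(NA_integer_, nrow(sub))
  for (i in seq_len(nrow(sub))) {
    if (anyNA(sub[i, ])) next
    lab <- risk[paste(sub[i, ], collapse = "|")]
    pred[i] <- if (!is.na(lab) && lab == "HIGH") 1L else 0L
  }
  pred
}

o_confusion <- function(status, pred) {
  keep <- !is.na(pred)
  c(tp = sum(keep & pred == 1 & status == 1),
    tn = sum(keep & pred == 0 & status == 0),
    fp = sum(keep & pred == 1 & status == 0),
    fn = sum(keep & pred == 0 & status == 1))
}

o_eval <- function(geno, status, loci, threshold = NULL, equal = "HR") {
  counts <- o_counts(geno, status, loci)
  risk <- o_risk(counts, threshold, equal)
  cc <- o_confusion(status, o_classify(risk, geno, loci))
  list(risk = risk,
       ba = o_ba(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]]))
}

o_search <- function(geno, status, k, threshold = NULL, equal = "HR") {
  combos <- utils::combn(ncol(geno), k)
  ba <- numeric(ncol(combos))
  for (i in seq_len(ncol(combos)))
    ba[i] <- o_eval(geno, status, combos[, i], threshold, equal)$ba
  ord <- order(-ba, seq_along(ba))    # lexicographic tie-break (combn order)
  list(loci = lapply(ord, function(i) combos[, i]), ba = ba[ord])
}

# Held-out balanced accuracy: attribution from the training rows, scoring
# on the test rows (unseen cells low).
o_heldout_ba <- function(geno, status, train, test, loci, threshold = NULL,
                         equal = "HR") {
  risk <- o_risk(o_counts(geno[train, , drop = FALSE], status[train], loci),
                 threshold, equal)
  cc <- o_confusion(status[test],
                    o_classify(risk, geno[test, , drop = FALSE], loci))
  o_ba(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]])
}

# End-to-end cross-validation reference, given the fold labels.
o_cv <- function(geno, status, folds, K, threshold = NULL, equal = "HR") {
  k <- max(folds)
  picked <- vector("list", K)
  heldout <- matrix(NA_real_, K, k)
  for (f in seq_len(k)) {
    train <- which(folds != f)
    test <- which(folds == f)
    for (lev in seq_len(K)) {
      best <- o_search(geno[train, , drop = FALSE], status[train], lev,
                       threshold, equal)$loci[[1L]]
      picked[[lev]][[f]] <- best
      heldout[lev, f] <- o_heldout_ba(geno, status, train, test, best,
                                      threshold, equal)
    }
  }
  out <- data.frame(level = seq_len(K), model = NA_character_,
                    classification = NA_real_, prediction = NA_real_,
                    consistency = NA_integer_)
  winners <- vector("list", K)
  for (lev in seq_len(K)) {
    keys <- vapply(picked[[lev]], paste, character(1), collapse = ",")
    tab <- table(keys)
    cand <- sort(names(tab)[tab == max(tab)])   # "a,b" sorts lexicographically
    cand_mat <- do.call(rbind, lapply(strsplit(cand, ","), as.integer))
    win <- cand_mat[do.call(order, as.data.frame(cand_mat))[1L], ]
    winners[[lev]] <- win
    hit <- keys == paste(win, collapse = ",")
    out$model[lev] <- paste(win, collapse = " ")
    out$consistency[lev] <- sum(hit)
    out$prediction[lev] <- mean(heldout[lev, hit], na.rm = TRUE)
    out$classification[lev] <- o_eval(geno, status, win, threshold, equal)$ba
  }
  final <- order(-out$prediction, -out$consistency, out$level)[1L]
  list(table = out, final_level = final, final_loci = winners[[final]])
}

# End-to-end three-way split reference, given the index sets.
o_3ws <- function(geno, status, parts, K, x, threshold = NULL, equal = "HR") {
  gtr <- geno[parts$train, , drop = FALSE]
  str_ <- status[parts$train]
  gte <- geno[parts$test, , drop = FALSE]
  ste <- status[parts$test]
  pool <- c(parts$train, parts$test)
  out <- data.frame(level = seq_len(K), model = NA_character_,
                    training = NA_real_, testing = NA_real_,
                    validation = NA_real_)
  for (lev in seq_len(K)) {
    sr <- o_search(gtr, str_, lev, threshold, equal)
    xx <- min(x, length(sr$loci))
    test_ba <- vapply(seq_len(xx), function(i)
      o_eval(gte, ste, sr$loci[[i]], threshold, equal)$ba, 0)
    best <- which.max(test_ba)
    win <- sr$loci[[best]]
    out$model[lev] <- paste(win, collapse = " ")
    out$training[lev] <- sr$ba[best]
    out$testing[lev] <- test_ba[best]
    out$validation[lev] <- o_heldout_ba(geno, status, pool, parts$validation,
                                        win, threshold, equal)
  }
  list(table = out,
       final_level = order(-out$validation, out$level)[1L])
}

# Convert package objects into oracle-comparable maps.
cells_to_map <- function(cells) {
  obs <- which(cells$ca + cells$co > 0)
  k <- length(cells$loci)
  g <- mdrkit:::.decode_key(obs, k, length(cells$levels))
  keys <- apply(matrix(cells$levels[g + 1L], ncol = k), 1L, paste,
                collapse = "|")
  out <- lapply(seq_along(obs), function(j)
    c(ca = as.numeric(cells$ca[obs[j]]), co = as.numeric(cells$co[obs[j]])))
  names(out) <- keys
  out[order(names(out))]
}

risk_to_map <- function(model) {
  obs <- which(model$observed)
  k <- length(model$loci)
  g <- mdrkit:::.decode_key(obs, k, length(model$levels))
  keys <- apply(matrix(model$levels[g + 1L], ncol = k), 1L, paste,
                collapse = "|")
  out <- ifelse(model$high[obs], "HIGH", "LOW")
  names(out) <- keys
  out[order(names(out))]
}
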