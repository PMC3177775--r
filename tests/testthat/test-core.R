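# Core MDR machinery: cell counting, risk attribution, balanced accuracy
# and the exhaustive search, cross-checked against the naive reference
# implementation in helper-oracle.R.

test_that("count_cells tabulates pure cells and validates its inputs", {
  d <- mdr_data(matrix(c(0, 0, 1, 1, 0, 0, 1, 1), ncol = 2),
                status = c(1, 1, 0, 0))
  cells <- count_cells(d, c(1, 2))
  m <- cells_to_map(cells)
  expect_equal(m[["0|0"]], c(ca = 2, co = 0))
  expect_equal(m[["1|1"]], c(ca = 0, co = 2))
  expect_equal(length(m), 2L)
  expect_equal(cells$n_used, 4L)

  expect_error(count_cells(d, integer(0)), "at least one locus")
  expect_error(count_cells(d, c(1, 5)), "5")
  expect_error(count_cells(d, c(2, 2)), "duplicate.*2")
})

test_that("cell counts match a per-row tally and conserve individuals", {
  set.seed(11)
  for (rep in 1:20) {
    d <- rand_data(sample(20:50, 1), sample(2:5, 1),
                   miss = sample(c(0, 0.05), 1))
    loci <- sample(ncol(d$code), sample(1:2, 1))
    cells <- count_cells(d, loci)
    expect_identical(cells_to_map(cells),
                     o_counts(d$genotypes, d$status, loci)[
                       order(names(o_counts(d$genotypes, d$status, loci)))])
    n_complete <- sum(!apply(d$genotypes[, loci, drop = FALSE], 1, anyNA))
    expect_equal(sum(cells$ca) + sum(cells$co), n_complete)
  }
})

test_that("risk attribution follows the ratio threshold and tie rule", {
  d <- mdr_data(matrix(c(rep(0, 4), rep(1, 4), rep(2, 4)), ncol = 1),
                status = c(1, 1, 1, 0,  1, 1, 0, 0,  0, 0, 0, 1))
  cells <- count_cells(d, 1)
  # cells: geno 0 -> 3 cases/1 control, geno 1 -> 2/2, geno 2 -> 1/3
  m <- risk_to_map(attribute_risk(cells, ratio = 1))
  expect_equal(unname(m[c("0", "1", "2")]), c("HIGH", "HIGH", "LOW"))
  m <- risk_to_map(attribute_risk(cells, ratio = 1, equal = "LR"))
  expect_equal(unname(m["1"]), "LOW")

  # zero-control cells are HIGH, zero-case cells LOW, unseen cells EMPTY
  d2 <- mdr_data(matrix(c(0, 0, 1, 1), ncol = 1), status = c(1, 1, 0, 0))
  r2 <- attribute_risk(count_cells(d2, 1))
  expect_equal(unname(risk_to_map(r2)), c("HIGH", "LOW"))
  expect_false(r2$observed[3])
  expect_false(r2$high[3])

  expect_error(attribute_risk(cells, ratio = 0), "positive")
  expect_error(attribute_risk(cells, ratio = -1), "positive")
})

test_that("balanced-data attribution equals a sign comparison of counts", {
  set.seed(21)
  for (rep in 1:20) {
    d <- rand_data(40, 3)          # 20 cases / 20 controls -> auto T = 1
    loci <- sample(3, sample(1:2, 1))
    model <- attribute_risk(count_cells(d, loci))
    counts <- o_counts(d$genotypes, d$status, loci)
    want <- vapply(counts, function(x)
      if (x[["ca"]] > x[["co"]]) "HIGH"
      else if (x[["ca"]] < x[["co"]]) "LOW" else "HIGH", "")
    expect_identical(risk_to_map(model), want[order(names(want))])
  }
})

test_that("classify follows cell labels and the empty-cell policy", {
  train <- mdr_data(matrix(c(0, 0, 1, 1, 0, 0, 1, 1), ncol = 2),
                    status = c(1, 1, 0, 0))
  model <- attribute_risk(count_cells(train, c(1, 2)))
  new <- mdr_data(matrix(c(0, 1, 0, 0, 1, 2), ncol = 2),
                  status = c(1, 0, 0))
  expect_equal(classify(model, new), c(1L, 0L, 0L))            # unseen -> low
  expect_equal(classify(model, new, empty = "exclude"),
               c(1L, 0L, NA))
  bad <- mdr_data(matrix(0:3, ncol = 2), status = c(1, 0), levels = 0:3)
  expect_error(classify(model, bad), "level set")
})

test_that("training confusion counts equal the per-cell sums", {
  set.seed(31)
  for (rep in 1:10) {
    d <- rand_data(50, 4)
    loci <- sample(4, 2)
    cells <- count_cells(d, loci)
    model <- attribute_risk(cells)
    cc <- confusion_counts(d$status, classify(model, d))
    expect_equal(cc$TP, sum(cells$ca[model$high]))
    expect_equal(cc$FN, sum(cells$ca[!model$high & model$observed]))
    expect_equal(cc$TN, sum(cells$co[!model$high & model$observed]))
    expect_equal(cc$FP, sum(cells$co[model$high]))
  }
})

test_that("balanced accuracy matches its definition and bounds", {
  expect_equal(balanced_accuracy(10, TN = 10, FP = 0, FN = 0), 1.0)
  expect_equal(balanced_accuracy(10, TN = 10, FP = 10, FN = 10), 0.5)
  expect_equal(balanced_accuracy(8, TN = 3, FP = 7, FN = 2), 0.55)
  expect_error(balanced_accuracy(0, TN = 5, FP = 5, FN = 0), "cases")
  expect_error(balanced_accuracy(5, TN = 0, FP = 0, FN = 5), "controls")

  # BA = 1 iff no misclassification; always within [0, 1]
  set.seed(41)
  for (rep in 1:20) {
    d <- rand_data(30, 3)
    ev <- evaluate_combination(d, sample(3, 1))
    expect_gte(ev$ba, 0)
    expect_lte(ev$ba, 1)
    cc <- confusion_counts(d$status, classify(ev$model, d))
    expect_equal(ev$ba == 1, cc$FN == 0 && cc$FP == 0)
  }
})

test_that("evaluate_combination separates XOR data and matches the oracle", {
  expect_equal(evaluate_combination(xor_data(), c(1, 2))$ba, 1.0)
  set.seed(51)
  for (rep in 1:10) {
    d <- rand_data(30, 4)
    loci <- sample(4, 2)
    ev <- evaluate_combination(d, loci)
    o <- o_eval(d$genotypes, d$status, loci)
    expect_equal(ev$ba, o$ba, tolerance = 1e-12)
    expect_identical(risk_to_map(ev$model), o$risk[order(names(o$risk))])
  }
})

test_that("status independent of genotype gives chance-level accuracy", {
  set.seed(61)
  d <- rand_data(4000, 2)
  expect_lt(abs(evaluate_combination(d, c(1, 2))$ba - 0.5), 0.03)
})

test_that("exhaustive search enumerates, ranks and ties deterministically", {
  set.seed(71)
  d <- rand_data(30, 3)
  expect_equal(nrow(mdr_search(d, k = 2)), 3L)     # C(3,2)
  expect_error(mdr_search(d, k = 4), "between 1")

  for (rep in 1:10) {
    d <- rand_data(sample(20:40, 1), 6)
    r <- mdr_search(d, k = 2)
    o <- o_search(d$genotypes, d$status, 2)
    expect_identical(lapply(r$loci, as.integer), o$loci)
    expect_equal(r$ba, o$ba, tolerance = 1e-12)
  }
})

test_that("an embedded signal pair is ranked first", {
  d <- simulate_mdr(sim_spec(100, 100, 10, maf = 0.5, causal = c(4, 9),
                             penetrance = xor_penetrance(0.1, 0.5)),
                    seed = 9)
  expect_equal(mdr_search(d, k = 2)$loci[[1]], c(4L, 9L))
})

test_that("label-swap symmetry: swapping strata and inverting the threshold flips risk", {
  set.seed(81)
  for (rep in 1:10) {
    d <- rand_data(40, 3)
    loci <- sample(3, 2)
    t <- runif(1, 0.5, 2)
    a <- evaluate_combination(d, loci, ratio = t, equal = "HR")
    sw <- mdr_data(d$genotypes, status = 1L - d$status)
    b <- evaluate_combination(sw, loci, ratio = 1 / t, equal = "LR")
    ra <- risk_to_map(a$model)
    rb <- risk_to_map(b$model)
    expect_identical(ra == "HIGH", rb == "LOW")
    expect_equal(a$ba, b$ba, tolerance = 1e-12)
  }
})

test_that("core fitting is deterministic (no hidden randomness)", {
  set.seed(91)
  d <- rand_data(40, 5)
  r1 <- mdr_search(d, k = 2)
  set.seed(12345)   # unrelated RNG state must not matter
  r2 <- mdr_search(d, k = 2)
  expect_identical(r1, r2)
})

test_that("delimited datasets round-trip through write and read", {
  set.seed(101)
  d <- rand_data(30, 4, miss = 0.05)
  for (sep in c(",", "\t")) {
    path <- tempfile(fileext = ".txt")
    write_mdr_data(d, path, sep = sep)
    back <- read_mdr_data(path)       # separator auto-detected
    expect_identical(back$status, d$status)
    expect_identical(back$code, d$code)
    expect_identical(back$locus_names, d$locus_names)
  }
  bad <- tempfile()
  writeLines("status", bad)
  expect_error(read_mdr_data(bad), "genotype column")
})
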