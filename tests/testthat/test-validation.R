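# Internal validation: fold/split construction, the cross-validation and
# three-way-split pipelines (cross-checked end-to-end against the oracle
# at small scale), and prediction on new data.

test_that("folds are stratified, balanced and reproducible", {
  d <- rand_data_fixed <- {
    set.seed(1)
    rand_data(10, 2)
  }
  f <- assign_folds(d, k = 5, seed = 3)
  for (fold in 1:5) {
    expect_equal(sum(f == fold & d$status == 1L), 1L)
    expect_equal(sum(f == fold & d$status == 0L), 1L)
  }
  expect_identical(f, assign_folds(d, k = 5, seed = 3))
  expect_error(assign_folds(d, k = 6), "stratum")
})

test_that("folds partition every dataset with stratum sizes within one", {
  set.seed(2)
  for (rep in 1:50) {
    d <- rand_data(sample(12:40, 1), 2)
    k <- sample(2:4, 1)
    f <- assign_folds(d, k)
    expect_equal(sort(unique(f)), 1:k)
    expect_equal(length(f), nrow(d$code))
    for (s in 0:1) {
      sizes <- tabulate(f[d$status == s], k)
      expect_lte(max(sizes) - min(sizes), 1L)
    }
  }
})

test_that("three-way split hits exact proportions and partitions the data", {
  set.seed(3)
  d <- rand_data(100, 2)
  s <- split_three_way(d, proportion = c(2, 1, 1), seed = 5)
  expect_equal(lengths(s), c(train = 50L, test = 25L, validation = 25L))
  expect_identical(s, split_three_way(d, proportion = c(2, 1, 1), seed = 5))

  for (rep in 1:30) {
    d <- rand_data(sample(20:60, 1), 2)
    s <- split_three_way(d, proportion = runif(3, 0.5, 3))
    all_idx <- sort(c(s$train, s$test, s$validation))
    expect_identical(all_idx, seq_len(nrow(d$code)))   # disjoint + exhaustive
  }
  tiny <- {
    set.seed(4)
    rand_data(4, 2)
  }
  expect_error(split_three_way(tiny, proportion = c(50, 1, 1)), "empty")
})

test_that("cross-validation fit matches an independent fold-by-fold script", {
  for (seed in c(101, 102, 103)) {
    set.seed(seed)
    d <- rand_data(40, 3)
    fit <- mdr_cv(d, K = 2, cv = 2, seed = seed)
    folds <- assign_folds(d, k = 2, seed = seed)
    o <- o_cv(d$genotypes, d$status, folds, K = 2)
    expect_equal(fit$table$model, o$table$model)
    expect_equal(fit$table$classification, o$table$classification,
                 tolerance = 1e-12)
    expect_equal(fit$table$prediction, o$table$prediction, tolerance = 1e-12)
    expect_equal(fit$table$consistency, o$table$consistency)
    expect_equal(fit$final_level, o$final_level)
    expect_equal(fit$final_loci, o$final_loci)
  }
})

test_that("a strong embedded pair is selected with full consistency", {
  d <- simulate_mdr(sim_spec(150, 150, 8, maf = 0.5, causal = c(2, 5),
                             penetrance = xor_penetrance(0.1, 0.5)),
                    seed = 17)
  fit <- mdr_cv(d, K = 3, cv = 5, seed = 17)
  expect_equal(fit$final_loci, c(2L, 5L))
  expect_equal(fit$table$consistency[2], 5L)
  expect_lte(max(fit$table$consistency), 5L)
})

test_that("pure-noise data yields chance-level prediction accuracy", {
  accs <- vapply(1:8, function(s) {
    d <- simulate_mdr(sim_spec(60, 60, 4, penetrance = 0.5), seed = 200 + s)
    mean(mdr_cv(d, K = 2, cv = 5, seed = s)$table$prediction)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("training accuracy exceeds held-out accuracy on average (selection bias)", {
  set.seed(7)
  gap <- vapply(1:20, function(i) {
    d <- rand_data(60, 4)
    fit <- mdr_cv(d, K = 2, cv = 3)
    mean(fit$table$classification) - mean(fit$table$prediction)
  }, 0)
  expect_gt(mean(gap), 0)
})

test_that("three-way split fit matches an independent stage-by-stage script", {
  for (seed in c(301, 302, 303)) {
    set.seed(seed)
    d <- rand_data(60, 4)
    fit <- mdr_3ws(d, K = 2, x = 2, proportion = c(2, 2, 1), seed = seed)
    parts <- split_three_way(d, proportion = c(2, 2, 1), seed = seed)
    o <- o_3ws(d$genotypes, d$status, parts, K = 2, x = 2)
    expect_equal(fit$table$model, o$table$model)
    expect_equal(fit$table$training, o$table$training, tolerance = 1e-12)
    expect_equal(fit$table$testing, o$table$testing, tolerance = 1e-12)
    expect_equal(fit$table$validation, o$table$validation, tolerance = 1e-12)
    expect_equal(fit$final_level, o$final_level)
  }
})

test_that("x = 1 carries only the training winner, and oversized x is clamped", {
  set.seed(8)
  d <- rand_data(60, 4)
  fit1 <- mdr_3ws(d, K = 2, x = 1, proportion = c(2, 2, 1), seed = 8)
  parts <- split_three_way(d, proportion = c(2, 2, 1), seed = 8)
  tr <- parts$train
  best_train <- o_search(d$genotypes[tr, , drop = FALSE], d$status[tr], 2)
  expect_equal(fit1$table$model[2],
               paste(best_train$loci[[1]], collapse = " "))
  w <- capture_warnings(mdr_3ws(d, K = 2, x = 100, seed = 8))
  expect_true(any(grepl("clamped", w)))
})

test_that("a strong three-locus signal wins the validation stage", {
  pen <- array(0.05, dim = c(3, 3, 3))
  pen[ (slice.index(pen, 1) + slice.index(pen, 2) + slice.index(pen, 3)) %% 2 == 0 ] <- 0.6
  d <- simulate_mdr(sim_spec(250, 250, 6, maf = 0.5, causal = c(1, 3, 5),
                             penetrance = pen), seed = 23)
  fit <- mdr_3ws(d, K = 3, x = 5, seed = 23)
  expect_equal(fit$final_level, 3L)
  expect_equal(sort(fit$final_loci), c(1L, 3L, 5L))
  expect_equal(which.max(fit$table$validation), 3L)
})

test_that("validation fits are reproducible end-to-end for a fixed seed", {
  set.seed(9)
  d <- rand_data(50, 5)
  f1 <- mdr_cv(d, K = 2, cv = 5, seed = 42)
  f2 <- mdr_cv(d, K = 2, cv = 5, seed = 42)
  expect_identical(f1$table, f2$table)
  g1 <- mdr_3ws(d, K = 2, x = 3, seed = 42)
  g2 <- mdr_3ws(d, K = 2, x = 3, seed = 42)
  expect_identical(g1$table, g2$table)
})

test_that("predict is self-consistent on the training data and on new draws", {
  spec <- sim_spec(100, 100, 6, maf = 0.5, causal = c(1, 4),
                   penetrance = xor_penetrance(0.1, 0.4))
  d <- simulate_mdr(spec, seed = 31)
  fit <- mdr_cv(d, K = 2, cv = 5, seed = 31)
  pr <- predict(fit, d)
  expect_equal(pr$ba, fit$table$classification[fit$final_level],
               tolerance = 1e-12)

  # one individual sitting in a known high-risk cell
  hi <- which(classify(fit$final_model, d) == 1L)[1]
  one <- mdr_data(d$genotypes[hi, , drop = FALSE], status = 1L,
                  locus_names = d$locus_names)
  expect_equal(predict(fit, one)$labels, 1L)

  # fresh draw from the same generative model predicts above chance
  d2 <- simulate_mdr(spec, seed = 32)
  expect_gt(predict(fit, d2)$ba, 0.6)

  expect_error(predict(fit, d$genotypes[, 1:3]), "loci")
})
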