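test_that("fold assignments are deterministic and respect the 75% rule", {
  tens <- rand_tensor(12, 12, 3, seed = 1)
  fa1 <- assign_folds(tens, seed = 42)
  fa2 <- assign_folds(tens, seed = 42)
  expect_identical(fa1$folds, fa2$folds)
  expect_false(identical(fa1$folds, assign_folds(tens, seed = 43)$folds))
  expect_true(all(sort(unique(as.vector(fa1$folds))) %in% 0:5))
  for (f in 1:5) {
    expect_true(all(rowSums(fa1$folds == f) <= 0.75 * rowSums(tens$observed)))
    expect_true(all(colSums(fa1$folds == f) <= 0.75 * colSums(tens$observed)))
  }
})

test_that("boundary semantics: 75% exactly is allowed, more is not", {
  # a drug observed in exactly 4 cells: folds may hold up to 3 of them
  tens <- rand_tensor(8, 6, 3, seed = 2)
  tens <- tensor_unobserve(tens, cbind("d01", c("c05", "c06")))
  for (seed in 1:20) {
    fa <- assign_folds(tens, seed = seed)
    per_fold <- tabulate(fa$folds["d01", fa$folds["d01", ] > 0],
                         nbins = 5)
    expect_true(all(per_fold <= 3))
  }
})

test_that("unsatisfiable margins error out", {
  tens <- rand_tensor(4, 4, 2, seed = 3)
  tens <- tensor_unobserve(tens, cbind("d01", c("c02", "c03", "c04")))
  expect_error(assign_folds(tens, seed = 1), ">= 2")
})

test_that("accepted assignments stay uniform across folds", {
  tens <- rand_tensor(12, 12, 2, seed = 4)
  counts <- numeric(5)
  for (seed in 1:300) {
    fa <- assign_folds(tens, seed = seed)
    counts <- counts + tabulate(fa$folds[fa$folds > 0], nbins = 5)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("cross-validation imputes exactly the observed pairs", {
  tens <- rand_tensor(10, 5, 8, miss_frac = 0.2, seed = 5)
  fa <- assign_folds(tens, seed = 11)
  cv <- run_cross_validation(tens, "mom", fa)
  expect_identical(cv$imputed$observed, tens$observed)
  nas_per_pair <- apply(is.na(cv$imputed$values), c(1, 2), sum)
  expect_true(all(nas_per_pair[cv$imputed$observed] == 0L))
  expect_true(all(nas_per_pair[!cv$imputed$observed] ==
                    length(tens$genes)))
  expect_identical(nrow(cv$failures), 0L)
})

test_that("the training tensor physically excludes the evaluated fold (taint)", {
  tens <- rand_tensor(8, 4, 6, seed = 6)
  fa <- assign_folds(tens, seed = 3)
  # oracle-leak double: tries to read its own target pair from the
  # training input; must fail on every pair
  leak <- function(train, drug, cell, state) tensor_profile(train, drug,
                                                            cell)
  cv <- run_cross_validation(tens, leak, fa, fallback_ta = FALSE)
  expect_identical(nrow(cv$failures), sum(tens$observed))
  expect_true(all(grepl("not observed", cv$failures$error)))
  expect_identical(sum(cv$imputed$observed), 0L)
})

test_that("TA over a constant tensor reproduces it; WSpe = 1 downstream", {
  const <- tensor_from_fn(6, 4, 10, function(i, j, g) (g %% 3) - 1)
  fa <- assign_folds(const, seed = 2)
  cv <- run_cross_validation(const, "ta", fa)
  expect_tensor_equal(cv$imputed, const)
  sc <- score_connectivity_agreement(const, cv$imputed, "c01",
                                     polarity = "negative", k = 2,
                                     epsilon = 0.2)
  expect_equal(unname(sc$mean), 1)
})

test_that("failed pairs fall back to TA and are reported, never silent", {
  tens <- rand_tensor(6, 4, 5, seed = 13)
  fail_once <- function(train, drug, cell, state) {
    if (drug == "d01") stop("boom") else impute_mom(train, drug, cell)
  }
  cv <- run_cross_validation(tens, fail_once, fa <- assign_folds(tens, 9))
  expect_true(all(cv$failures$drug == "d01"))
  expect_true(all(cv$failures$fallback))
  expect_identical(cv$imputed$observed, tens$observed)
})

test_that("weighted Spearman matches the direct-formula oracle", {
  # identical rankings
  set.seed(20)
  sc <- setNames(rnorm(10), sprintf("d%02d", 1:10))
  expect_equal(weighted_spearman(sc, sc, 0.01), 1)
  # exactly reversed rankings, n = 10: negative, equal to the oracle
  rev_sc <- setNames(-sc, names(sc))
  w <- weighted_spearman(sc, rev_sc, epsilon = 0.01)
  expect_lt(w, 0)
  expect_equal(w, oracle_wspe(sc, rev_sc, 0.01), tolerance = 1e-12)
  # random rankings, both polarities, several epsilons
  for (seed in 1:10) {
    set.seed(seed)
    a <- setNames(rnorm(30), sprintf("d%02d", 1:30))
    b <- setNames(rnorm(30), names(a))
    for (eps in c(0.05, 0.2, 0.8)) {
      for (pol in c("positive", "negative")) {
        expect_equal(weighted_spearman(a, b, eps, pol),
                     oracle_wspe(a, b, eps, pol), tolerance = 1e-12)
      }
    }
  }
})

test_that("agreement in the top 20 of 450 dominates WSpe at epsilon 0.01", {
  set.seed(30)
  true <- setNames(sort(rnorm(450), decreasing = TRUE),
                   sprintf("d%03d", 1:450))
  imp <- true
  # shuffle everything below rank 20 (positive polarity ranking)
  tail_names <- names(true)[21:450]
  imp[tail_names] <- sample(unname(true[tail_names]))
  w <- weighted_spearman(true, imp, epsilon = 0.01, polarity = "positive")
  expect_gt(w, 0.95)
  expect_equal(w, oracle_wspe(true, imp, 0.01, "positive"),
               tolerance = 1e-12)
  # the same amount of disagreement in the head is catastrophic instead
  imp2 <- true
  head_names <- names(true)[1:20]
  set.seed(33)
  imp2[head_names] <- sample(unname(true[head_names]))
  expect_lt(weighted_spearman(true, imp2, 0.01, "positive"), 0.5)
  expect_gt(w, weighted_spearman(true, imp2, 0.01, "positive"))
})

test_that("WSpe flattens to classical Spearman for large epsilon", {
  set.seed(31)
  a <- setNames(rnorm(50), sprintf("d%02d", 1:50))
  b <- setNames(rnorm(50), names(a))
  rho <- stats::cor(rank(-a), rank(-b), method = "pearson")
  # sigma = n * epsilon must dwarf n for the weights to flatten, so the
  # check uses epsilon >> 1 (allowed outside the (0, 1) working range)
  expect_lt(abs(weighted_spearman(a, b, epsilon = 50) - rho), 1e-3)
})

test_that("WSpe is invariant to drug relabeling and rejects mismatches", {
  set.seed(32)
  a <- setNames(rnorm(15), sprintf("d%02d", 1:15))
  b <- setNames(rnorm(15), names(a))
  relabel <- setNames(sprintf("x%02d", 1:15), names(a))
  a2 <- setNames(unname(a), relabel[names(a)])
  b2 <- setNames(unname(b), relabel[names(b)])
  expect_equal(weighted_spearman(a, b, 0.1), weighted_spearman(a2, b2, 0.1))
  expect_error(weighted_spearman(a, b[1:10], 0.1), "same drug set")
})

test_that("five runs with different seeds give distinct assignments", {
  tens <- rand_tensor(10, 6, 3, seed = 7)
  folds <- lapply(1:5, function(s) assign_folds(tens, seed = s)$folds)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(identical(folds[[i]], folds[[j]]))
  }
})

test_that("downsampling keeps the requested count, deterministically", {
  tens <- rand_tensor(100, 3, 4, seed = 8)
  for (fr in c(0.5, 0.2, 0.1)) {
    down <- downsample_cell(tens, "c02", fr, seed = 5)
    expect_identical(sum(down$observed[, "c02"]), as.integer(100 * fr))
    expect_identical(sum(down$observed[, "c01"]), 100L)
  }
  expect_identical(downsample_cell(tens, "c02", 1, seed = 5), tens)
  d1 <- downsample_cell(tens, "c02", 0.3, seed = 9)
  d2 <- downsample_cell(tens, "c02", 0.3, seed = 9)
  expect_identical(d1$observed, d2$observed)
  tiny <- rand_tensor(8, 2, 3, seed = 9)
  expect_error(downsample_cell(tiny, "c01", 0.1, seed = 1), "< 2")
})
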