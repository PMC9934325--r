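test_that("tissue-agnostic imputation is the cross-cell median", {
  # gene 1 of d01 takes values 1, 5, 9 in the three non-target cells
  tens <- tensor_from_fn(2, 4, 2, function(i, j, g) {
    if (i == 1 && g == 1) c(99, 1, 5, 9)[j] else (i + j + g) / 10
  })
  pred <- impute_tissue_agnostic(tens, "d01", "c01")
  expect_equal(unname(pred["g001"]), 5)
  # even count: median of (2, 4) = 3
  tens2 <- tensor_from_fn(2, 3, 1, function(i, j, g) {
    if (i == 1) c(99, 2, 4)[j] else 0
  })
  expect_equal(unname(impute_tissue_agnostic(tens2, "d01", "c01")), 3)
  # constant tensor predicts the constant
  const <- tensor_from_fn(3, 3, 4, function(i, j, g) 2.5)
  expect_equal(unname(impute_tissue_agnostic(const, "d02", "c02")),
               rep(2.5, 4))
})

test_that("TA errors when the drug is observed nowhere else", {
  tens <- rand_tensor(3, 3, 4, seed = 1)
  tens <- tensor_unobserve(tens, cbind("d01", c("c02", "c03")))
  expect_error(impute_tissue_agnostic(tens, "d01", "c01"),
               class = "conncf_no_data")
})

test_that("median-of-medians averages the two marginal medians", {
  # row median 3, column median 5 -> prediction 4
  tens <- tensor_from_fn(3, 3, 1, function(i, j, g) {
    if (i == 1 && j > 1) 3 else if (i > 1 && j == 1) 5 else 0
  })
  expect_equal(unname(impute_mom(tens, "d01", "c01")), 4)
  # equal marginals return the common value
  const <- tensor_from_fn(3, 3, 2, function(i, j, g) -1.5)
  expect_equal(unname(impute_mom(const, "d02", "c03")), rep(-1.5, 2))
})

test_that("MoM equals the two-pass median oracle on a printed 3x3x1 fixture", {
  vals <- matrix(c(0.7, -1.2, 2.0,
                   1.4,  0.3, -0.8,
                   -2.1, 0.9,  1.1), 3, 3, byrow = TRUE)
  tens <- tensor_from_fn(3, 3, 1, function(i, j, g) vals[i, j])
  for (i in 1:3) for (j in 1:3) {
    d <- tens$drugs[i]; cl <- tens$cells[j]
    expect_equal(unname(impute_mom(tens, d, cl)),
                 unname(oracle_mom(tens, d, cl)), tolerance = 1e-12)
  }
})

test_that("adjusted cosine hits the hand-checkable cases", {
  dn <- axis_names(2, 1, 3)
  # identical fully observed rows
  arr <- array(c(1, 1, 2, 2, 3, 3), c(2, 1, 3), dimnames = dn)
  R <- reshape_tensor(expression_tensor(arr))
  sim <- drug_similarity(R, min_overlap = 1)
  expect_equal(sim["d01", "d02"], 1)
  expect_equal(unname(diag(sim)), c(1, 1))
  # row 2 the negation of (already centered) row 1
  arr2 <- array(c(1, -1, 0, 0, -1, 1), c(2, 1, 3), dimnames = dn)
  R2 <- reshape_tensor(expression_tensor(arr2))
  expect_equal(drug_similarity(R2, min_overlap = 1)["d01", "d02"], -1)
  # centered co-observed values (1, 0, -1) vs (2, 0, -2)
  arr3 <- array(c(1, 2, 0, 0, -1, -2), c(2, 1, 3), dimnames = dn)
  R3 <- reshape_tensor(expression_tensor(arr3))
  expect_equal(drug_similarity(R3, min_overlap = 1)["d01", "d02"], 1)
})

test_that("similarity is symmetric, bounded, and respects min_overlap", {
  tens <- rand_tensor(8, 5, 6, miss_frac = 0.35, seed = 6)
  R <- reshape_tensor(tens)
  sim <- drug_similarity(R, min_overlap = 6)
  expect_equal(sim, t(sim))
  expect_true(all(abs(sim[!is.na(sim)]) <= 1))
  overlap <- tcrossprod(!is.na(R$values) + 0)
  expect_true(all(is.na(sim[overlap < 6])))
})

test_that("NCF reproduces a duplicate neighbor exactly with k = 1", {
  tens <- rand_tensor(5, 3, 8, seed = 12)
  # d05 duplicates d02 outside the target cell, so it is the top neighbor;
  # with k = 1 the prediction is d05's profile in the target cell
  tens$values["d05", "c02", ] <- tens$values["d02", "c02", ]
  tens$values["d05", "c03", ] <- tens$values["d02", "c03", ]
  R <- reshape_tensor(tens)
  pred <- impute_ncf(R, "d02", "c01", ncf_params(k_neighbors = 1,
                                                 min_overlap = 1))
  expect_equal(unname(c(pred)), unname(tens$values["d05", "c01", ]),
               tolerance = 1e-12)
  expect_identical(attr(pred, "neighbors")$drug, "d05")
})

test_that("NCF weighting follows sim / sum(|sim|)", {
  tens <- rand_tensor(3, 2, 2, seed = 3)
  tens$values["d02", "c01", ] <- c(2, 2)
  tens$values["d03", "c01", ] <- c(4, 4)
  R <- reshape_tensor(tens)
  mock_sim <- function(s2, s3) {
    m <- matrix(NA_real_, 3, 3, dimnames = list(R$drugs, R$drugs))
    m["d01", "d02"] <- m["d02", "d01"] <- s2
    m["d01", "d03"] <- m["d03", "d01"] <- s3
    diag(m) <- 1
    m
  }
  # equal positive weights -> plain mean
  pred <- impute_ncf(R, "d01", "c01", ncf_params(k_neighbors = 2),
                     similarities = mock_sim(1, 1))
  expect_equal(unname(c(pred)), c(3, 3))
  # signed weights with |.| normalization: (0.5*4 + -0.5*4) / 1 = 0
  tens2 <- tens
  tens2$values["d02", "c01", ] <- c(4, 4)
  R2 <- reshape_tensor(tens2)
  pred2 <- impute_ncf(R2, "d01", "c01", ncf_params(k_neighbors = 2),
                      similarities = mock_sim(0.5, -0.5))
  expect_equal(unname(c(pred2)), c(0, 0))
})

test_that("NCF is invariant to drug ordering", {
  tens <- rand_tensor(10, 4, 6, seed = 21)
  R <- reshape_tensor(tens)
  p1 <- impute_ncf(R, "d04", "c02", ncf_params(k_neighbors = 3,
                                               min_overlap = 1))
  p1 <- c(p1)
  perm <- rev(tens$drugs)
  tens2 <- expression_tensor(tens$values[perm, , , drop = FALSE],
                             observed = tens$observed[perm, ,
                                                      drop = FALSE])
  p2 <- c(impute_ncf(reshape_tensor(tens2), "d04", "c02",
                     ncf_params(k_neighbors = 3, min_overlap = 1)))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("NCF errors when no neighbor is eligible", {
  tens <- rand_tensor(3, 3, 4, miss_frac = 0, seed = 4)
  # nobody else observed in the target cell
  tens <- tensor_unobserve(tens, cbind(c("d02", "d03"), "c01"))
  R <- reshape_tensor(tens)
  expect_error(impute_ncf(R, "d01", "c01", ncf_params(min_overlap = 1)),
               class = "conncf_no_neighbors")
})

test_that("similarity excludes the target cell's columns (no leakage)", {
  tens <- rand_tensor(4, 3, 5, seed = 8)
  R <- reshape_tensor(tens)
  sim_with <- drug_similarity(R, min_overlap = 1)
  sim_wo <- drug_similarity(R, min_overlap = 1, exclude_cell = "c02")
  # planting a perfect copy inside the excluded cell must not move the
  # excluded-cell similarity
  tens2 <- tens
  tens2$values["d02", "c02", ] <- tens2$values["d01", "c02", ]
  sim_wo2 <- drug_similarity(reshape_tensor(tens2), min_overlap = 1,
                             exclude_cell = "c02")
  expect_equal(sim_wo["d01", "d02"], sim_wo2["d01", "d02"],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sim_with["d01", "d02"],
                                sim_wo["d01", "d02"])))
})
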