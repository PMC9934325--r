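# Programmatic fixtures (no files on disk; everything is built in code).

axis_names <- function(nd, nc, ng) {
  list(sprintf("d%02d", seq_len(nd)), sprintf("c%02d", seq_len(nc)),
       sprintf("g%03d", seq_len(ng)))
}

# Random tensor with an optional fraction of (drug, cell) pairs missing.
rand_tensor <- function(nd, nc, ng, miss_frac = 0, seed = 1) {
  dn <- axis_names(nd, nc, ng)
  set.seed(seed)
  arr <- array(rnorm(nd * nc * ng), c(nd, nc, ng), dimnames = dn)
  if (miss_frac > 0) {
    n_miss <- floor(miss_frac * nd * nc)
    # keep every drug/cell with >= 1 observation so the tensor stays usable
    repeat {
      obs <- matrix(TRUE, nd, nc)
      obs[sample.int(nd * nc, n_miss)] <- FALSE
      if (all(rowSums(obs) >= 1L) && all(colSums(obs) >= 1L)) break
    }
    for (j in seq_len(nc)) arr[!obs[, j], j, ] <- NA_real_
  }
  expression_tensor(arr)
}

# Tensor whose (drug, cell, gene) values follow an explicit function, handy
# for hand-checkable imputation cases.
tensor_from_fn <- function(nd, nc, ng, fn) {
  dn <- axis_names(nd, nc, ng)
  arr <- array(0, c(nd, nc, ng), dimnames = dn)
  for (i in seq_len(nd)) for (j in seq_len(nc)) for (g in seq_len(ng)) {
    arr[i, j, g] <- fn(i, j, g)
  }
  expression_tensor(arr)
}

expect_tensor_equal <- function(a, b, tol = 0) {
  expect_true(tensor_equal(a, b, tol = tol))
}
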