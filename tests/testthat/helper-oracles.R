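# Independent brute-force oracles.  These deliberately share no code with
# the package: plain loops, no vectorized shortcuts, so agreement with the
# implementation is meaningful.

# Weighted-KS enrichment score by explicit walk over the ranked list.
oracle_es <- function(profile, gene_set, p = 1) {
  nm <- names(profile)
  ord <- order(-profile, nm, method = "radix")
  z <- profile[ord]
  nm <- nm[ord]
  n <- length(z)
  in_set <- nm %in% gene_set
  ns <- sum(in_set)
  nr <- 0
  for (i in seq_len(n)) if (in_set[i]) nr <- nr + abs(z[i])^p
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      run <- run + (if (nr > 0) abs(z[i])^p / nr else 1 / ns)
    } else {
      run <- run - 1 / (n - ns)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Classical (unweighted) two-sample KS signed statistic: step 1/ns on set
# members, 1/(n-ns) on the rest, signed maximum deviation.
oracle_classical_ks <- function(profile, gene_set) {
  nm <- names(profile)
  ord <- order(-profile, nm, method = "radix")
  in_set <- nm[ord] %in% gene_set
  n <- length(in_set)
  ns <- sum(in_set)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + (if (in_set[i]) 1 / ns else -1 / (n - ns))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Weighted Pearson correlation of rank vectors by the direct formula.
oracle_wspe <- function(true_scores, imputed_scores, epsilon,
                        polarity = "positive") {
  n <- length(true_scores)
  s <- if (polarity == "positive") -1 else 1
  rt <- rank(s * true_scores, ties.method = "average")
  ri <- rank(s * imputed_scores[names(true_scores)],
             ties.method = "average")
  w <- numeric(n)
  for (i in seq_len(n)) {
    sigma <- n * epsilon
    w[i] <- 2 * exp(-rt[i]^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  }
  sw <- 0; sx <- 0; sy <- 0
  for (i in seq_len(n)) { sw <- sw + w[i]; sx <- sx + w[i] * rt[i];
                          sy <- sy + w[i] * ri[i] }
  mx <- sx / sw; my <- sy / sw
  cxy <- 0; vx <- 0; vy <- 0
  for (i in seq_len(n)) {
    cxy <- cxy + w[i] * (rt[i] - mx) * (ri[i] - my)
    vx <- vx + w[i] * (rt[i] - mx)^2
    vy <- vy + w[i] * (ri[i] - my)^2
  }
  unname(cxy / sqrt(vx * vy))
}

# Two-pass median prediction for median-of-medians imputation.
oracle_mom <- function(tensor, drug, cell) {
  genes <- tensor$genes
  out <- numeric(length(genes))
  names(out) <- genes
  for (g in genes) {
    row_vals <- c()
    for (cl in tensor$cells) {
      if (cl != cell && tensor$observed[drug, cl]) {
        row_vals <- c(row_vals, tensor$values[drug, cl, g])
      }
    }
    col_vals <- c()
    for (d in tensor$drugs) {
      if (d != drug && tensor$observed[d, cell]) {
        col_vals <- c(col_vals, tensor$values[d, cell, g])
      }
    }
    two <- c(median(row_vals), median(col_vals))
    out[g] <- median(two)
  }
  out
}

# Exhaustive drug-set enrichment null: every C(n, m) placement of the set
# over the ranked list, with the same sign-stratified NCS scaling and
# add-one p-value rule the package documents.
oracle_enrichment_exhaustive <- function(scores, members, p = 1) {
  ord <- order(-scores, names(scores), method = "radix")
  z <- scores[ord]
  n <- length(z)
  m <- length(members)
  es_one <- function(hit) {
    nr <- sum(abs(z[hit])^p)
    run <- 0; best <- 0
    for (i in seq_len(n)) {
      run <- run + (if (hit[i]) abs(z[i])^p / nr else -1 / (n - m))
      if (abs(run) > abs(best)) best <- run
    }
    unname(best)
  }
  obs_hit <- names(z) %in% members
  es_obs <- es_one(obs_hit)
  placements <- combn(n, m)
  es_all <- numeric(ncol(placements))
  for (k in seq_len(ncol(placements))) {
    h <- logical(n)
    h[placements[, k]] <- TRUE
    es_all[k] <- es_one(h)
  }
  mu_pos <- abs(mean(es_all[es_all > 0]))
  mu_neg <- abs(mean(es_all[es_all < 0]))
  scale1 <- function(x) {
    if (x > 0) x / mu_pos else if (x < 0) x / mu_neg else 0
  }
  ncs_obs <- scale1(es_obs)
  ncs_all <- vapply(es_all, scale1, numeric(1))
  pv <- if (ncs_obs == 0) 1 else {
    (1 + sum(abs(ncs_all) >= abs(ncs_obs))) / (1 + length(ncs_all))
  }
  list(es = es_obs, ncs = ncs_obs, p_value = pv, es_all = es_all)
}
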