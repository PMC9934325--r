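#' Constrained five-fold assignment of observed (drug, cell) pairs
#'
#' Every observed pair is assigned uniformly and independently to one of
#' `n_folds` folds; unobserved pairs get fold 0 and are never evaluated.
#' A candidate assignment is accepted only if *no* fold holds more than
#' `max_fraction` (default 75%) of any drug's observed cells, nor of any
#' cell's observed drugs -- exactly 75% is allowed ("more than" is strict).
#' This guarantees every imputation method has training data for every
#' withheld pair.  Violations trigger a complete regeneration (never a
#' local repair), up to `max_attempts`.
#'
#' @param tensor an `expression_tensor`; every drug must be observed in at
#'   least 2 cells and every cell for at least 2 drugs.
#' @param seed integer; assignments are deterministic given the seed.
#' @param n_folds number of folds (default 5).
#' @param max_fraction the constraint threshold (default 0.75).
#' @param max_attempts regeneration cap before erroring (default 10000).
#' @return A `fold_assignment`: list with `folds` (drug-by-cell integer
#'   matrix, 0 = unobserved), `n_folds`, `seed` and `attempts`.
#' @export
assign_folds <- function(tensor, seed, n_folds = 5L, max_fraction = 0.75,
                         max_attempts = 10000L) {
  obs <- tensor$observed
  drug_n <- rowSums(obs); cell_n <- colSums(obs)
  if (any(drug_n < 2L) || any(cell_n < 2L)) {
    stop(sprintf(
      "fold constraint needs every drug in >= 2 cells and every cell for >= 2 drugs (worst drug: %d cells, worst cell: %d drugs)",
      min(drug_n), min(cell_n)))
  }
  idx <- which(obs)
  folds <- matrix(0L, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      folds[idx] <- sample.int(n_folds, length(idx), replace = TRUE)
      ok <- TRUE
      for (f in seq_len(n_folds)) {
        inf <- folds == f
        if (any(rowSums(inf) > max_fraction * drug_n) ||
            any(colSums(inf) > max_fraction * cell_n)) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        return(structure(list(folds = folds, n_folds = as.integer(n_folds),
                              seed = seed, attempts = attempt),
                         class = "fold_assignment"))
      }
    }
    worst <- fold_margins(folds, obs, n_folds)
    stop(sprintf(
      "no valid fold assignment in %d attempts; tightest margins: %s",
      max_attempts, worst))
  })
}

fold_margins <- function(folds, obs, n_folds) {
  drug_n <- rowSums(obs); cell_n <- colSums(obs)
  fr <- sapply(seq_len(n_folds), function(f) {
    max(c(rowSums(folds == f) / pmax(drug_n, 1L),
          colSums(folds == f) / pmax(cell_n, 1L)))
  })
  sprintf("max per-fold fraction %.2f", max(fr))
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf(
    "fold_assignment: %d folds over %d observed pairs (seed %s, %d attempt%s)\n",
    x$n_folds, sum(x$folds > 0L), format(x$seed), x$attempts,
    if (x$attempts == 1L) "" else "s"))
  invisible(x)
}

#' Write / read a fold assignment as TSV (drug, cell, fold)
#'
#' Only observed pairs (fold > 0) are written.
#'
#' @param fa a `fold_assignment`.
#' @param path file path.
#' @export
write_folds <- function(fa, path) {
  idx <- which(fa$folds > 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(drug = rownames(fa$folds)[idx[, 1L]],
                   cell = colnames(fa$folds)[idx[, 2L]],
                   fold = fa$folds[idx], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve a method argument to an imputation closure
#   function(train_tensor, drug, cell) -> profile
# Strings get the package methods; NCF and SVD share per-fold state via
# the environment `state` the runner passes in.
resolve_method <- function(method, params) {
  if (is.function(method)) return(method)
  stopifnot(is.character(method), length(method) == 1L)
  switch(method,
    ta = function(train, drug, cell, state) {
      impute_tissue_agnostic(train, drug, cell)
    },
    mom = function(train, drug, cell, state) {
      impute_mom(train, drug, cell)
    },
    ncf = {
      p <- if (!is.null(params$ncf)) params$ncf else ncf_params()
      function(train, drug, cell, state) {
        if (is.null(state$R)) state$R <- reshape_tensor(train)
        key <- paste0("sim_", cell)
        if (is.null(state[[key]])) {
          state[[key]] <- drug_similarity(state$R,
                                          min_overlap = p$min_overlap,
                                          exclude_cell = cell)
        }
        impute_ncf(state$R, drug, cell, p, similarities = state[[key]])
      }
    },
    svd = {
      p <- if (!is.null(params$svd)) params$svd else svd_params()
      function(train, drug, cell, state) {
        if (is.null(state$fit)) {
          R <- reshape_tensor(train)
          pp <- p
          pp$rank <- min(pp$rank, dim(R$values))
          state$fit <- funk_svd_fit(R, pp)
        }
        funk_svd_predict(state$fit, drug, cell)
      }
    },
    stop(sprintf("unknown method '%s' (use ta, mom, ncf or svd)", method))
  )
}

#' Run constrained cross-validation of an imputation method
#'
#' For each fold f, the method is handed a *training* tensor in which every
#' fold-f pair has been blanked to unobserved (values removed, mask
#' cleared), and must impute every pair of fold f.  The union over folds
#' yields exactly one imputed profile per observed pair.  Because the
#' withheld values are physically absent from the training tensor, a method
#' cannot leak them; a method double that tries to read its own target pair
#' from the training input fails, which the test suite uses as a taint
#' check.  Per-pair method failures are recorded and the run continues.
#'
#' @param tensor the true `expression_tensor`.
#' @param method `"ta"`, `"mom"`, `"ncf"`, `"svd"`, or a function
#'   `function(train, drug, cell, state)` returning a gene profile
#'   (`state` is a per-fold environment for caching).
#' @param fold_assignment an [assign_folds()] result for `tensor`.
#' @param params list with optional elements `ncf` ([ncf_params()]) and
#'   `svd` ([svd_params()]).
#' @param fallback_ta when a pair fails (e.g. no eligible NCF neighbor),
#'   fall back to tissue-agnostic imputation instead of leaving the pair
#'   unimputed; fallbacks are reported in `failures`, never silent
#'   (default `TRUE`).
#' @return List with `imputed` (an `expression_tensor` whose observed mask
#'   equals the input's, holding imputed values), `failures` (data.frame of
#'   drug, cell, fold, error, fallback) and `provenance` (method name,
#'   fold seed).
#' @export
run_cross_validation <- function(tensor, method, fold_assignment,
                                 params = list(), fallback_ta = TRUE) {
  stopifnot(inherits(fold_assignment, "fold_assignment"))
  folds <- fold_assignment$folds
  stopifnot(identical(dimnames(folds), dimnames(tensor$observed)))
  impute_fn <- resolve_method(method, params)
  imputed <- tensor
  imputed$values[] <- NA_real_
  imputed$observed[] <- FALSE
  failures <- list()
  for (f in seq_len(fold_assignment$n_folds)) {
    pairs <- which(folds == f, arr.ind = TRUE)
    if (nrow(pairs) == 0L) next
    train <- tensor_unobserve(tensor, cbind(tensor$drugs[pairs[, 1L]],
                                            tensor$cells[pairs[, 2L]]))
    state <- new.env(parent = emptyenv())
    # impute cell-by-cell so NCF similarity caches are reused
    ord <- order(pairs[, 2L], pairs[, 1L])
    for (r in ord) {
      d <- tensor$drugs[pairs[r, 1L]]
      cl <- tensor$cells[pairs[r, 2L]]
      prof <- tryCatch(impute_fn(train, d, cl, state),
                       error = function(e) e)
      used_fallback <- FALSE
      if (inherits(prof, "error") && fallback_ta) {
        fallback <- tryCatch(impute_tissue_agnostic(train, d, cl),
                             error = function(e) e)
        if (!inherits(fallback, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            drug = d, cell = cl, fold = f,
            error = conditionMessage(prof), fallback = TRUE,
            stringsAsFactors = FALSE)
          prof <- fallback
          used_fallback <- TRUE
        }
      }
      if (inherits(prof, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          drug = d, cell = cl, fold = f,
          error = conditionMessage(prof), fallback = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      imputed <- tensor_set_profile(imputed, d, cl, unname(prof))
    }
  }
  failures <- if (length(failures) > 0L) {
    do.call(rbind, failures)
  } else {
    data.frame(drug = character(), cell = character(), fold = integer(),
               error = character(), fallback = logical(),
               stringsAsFactors = FALSE)
  }
  list(imputed = imputed, failures = failures,
       provenance = list(method = if (is.character(method)) method
                         else "custom",
                         fold_seed = fold_assignment$seed,
                         n_folds = fold_assignment$n_folds))
}

#' Head-weighted Spearman rank correlation (WSpe)
#'
#' Compares two rankings of the same drugs while concentrating on the head
#' of the *true* ranking.  Each drug's weight is `w(r) = 2 * dnorm(r, 0,
#' n * epsilon)` evaluated at its 1-based rank in the true list; with
#' `epsilon = 0.01` and n = 450 drugs, sigma = 4.5, so roughly the top 20
#' results carry non-negligible weight.  The statistic is the weighted
#' Pearson correlation of the two rank vectors (average ranks on ties) and
#' lies in \[-1, 1\]; as `epsilon` grows the weights flatten and WSpe tends
#' to the classical Spearman rho.
#'
#' @param true_scores,imputed_scores named numeric score vectors over the
#'   same drug set (n >= 2).
#' @param epsilon aggressiveness parameter, default 0.01; the working range
#'   is (0, 1) (sigma at most the list length), but any positive value is
#'   accepted -- sigma >> n flattens the weights and recovers classical
#'   Spearman, useful as a numerical check.
#' @param polarity `"positive"`: rank 1 = largest score; `"negative"`:
#'   rank 1 = smallest (most signature-reversing) score.
#' @return Scalar in \[-1, 1\].
#' @export
weighted_spearman <- function(true_scores, imputed_scores, epsilon = 0.01,
                              polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(epsilon > 0,
            !is.null(names(true_scores)), !is.null(names(imputed_scores)))
  if (!setequal(names(true_scores), names(imputed_scores)) ||
      length(true_scores) != length(imputed_scores)) {
    stop("true and imputed rankings must cover the same drug set")
  }
  n <- length(true_scores)
  if (n < 2L) stop("need at least two drugs")
  imputed_scores <- imputed_scores[names(true_scores)]
  s <- if (polarity == "positive") -1 else 1
  r_true <- rank(s * true_scores, ties.method = "average")
  r_imp <- rank(s * imputed_scores, ties.method = "average")
  w <- 2 * dnorm(r_true, mean = 0, sd = n * epsilon)
  weighted_pearson(r_true, r_imp, w)
}

weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 && vy <= 0) {
    # both rankings fully tied: identical orderings agree perfectly
    return(if (isTRUE(all.equal(x, y))) 1 else NA_real_)
  }
  if (vx <= 0 || vy <= 0) return(NA_real_)
  max(-1, min(1, cxy / sqrt(vx * vy)))
}

#' Connectivity agreement between a true and an imputed tensor
#'
#' For each drug observed in `cell`, builds the query signature from the
#' *true* profile, ranks all of the cell's drugs by WCS in the true tensor
#' and in the imputed tensor, and scores the agreement of the two rankings
#' with [weighted_spearman()].  The per-cell mean over query drugs is the
#' headline per-cell evaluation statistic.
#'
#' @param true_tensor,imputed_tensor `expression_tensor`s on the same axes;
#'   the imputed tensor must cover every drug observed in the cell.
#' @param cell cell identifier.
#' @param polarity passed to the ranking and to [weighted_spearman()].
#' @param k signature size per side (default 50, capped at half the gene
#'   axis).
#' @param epsilon WSpe aggressiveness (default 0.01).
#' @param p enrichment weight exponent.
#' @return List with `per_query` (named numeric, one WSpe per query drug)
#'   and `mean`.
#' @export
score_connectivity_agreement <- function(true_tensor, imputed_tensor, cell,
                                         polarity = c("positive",
                                                      "negative"),
                                         k = 50L, epsilon = 0.01, p = 1) {
  polarity <- match.arg(polarity)
  stopifnot(identical(true_tensor$genes, imputed_tensor$genes))
  k <- min(k, floor(length(true_tensor$genes) / 2))
  drugs <- true_tensor$drugs[true_tensor$observed[, cell]]
  if (length(drugs) < 2L) stop("need >= 2 observed drugs in the cell")
  if (!all(imputed_tensor$observed[drugs, cell])) {
    stop("imputed tensor lacks profiles for some of the cell's drugs")
  }
  per_query <- vapply(drugs, function(d) {
    sig <- extract_signature(true_tensor$values[d, cell, ], k = k)
    true_res <- query_connectivity(true_tensor, cell, sig, polarity, p)
    imp_res <- query_connectivity(imputed_tensor, cell, sig, polarity, p)
    t_sc <- stats::setNames(true_res$wcs, true_res$drug)[drugs]
    i_sc <- stats::setNames(imp_res$wcs, imp_res$drug)[drugs]
    weighted_spearman(t_sc, i_sc, epsilon = epsilon, polarity = polarity)
  }, numeric(1))
  list(per_query = per_query, mean = mean(per_query, na.rm = TRUE))
}

#' Downsample the observed drugs of one cell
#'
#' Randomly retains `round(fraction * n)` of the cell's observed drugs (the
#' rest become unobserved); other cells are untouched.  Used to chart how
#' much per-cell data an imputation method needs.
#'
#' @param tensor an `expression_tensor`.
#' @param cell cell identifier.
#' @param fraction fraction of observed drugs to keep, in (0, 1]; the
#'   canonical grid is 0.5, 0.4, 0.3, 0.2, 0.1.  `fraction = 1` returns the
#'   tensor unchanged.
#' @param seed integer; the retained set is deterministic given the seed.
#' @return The downsampled `expression_tensor`.
#' @export
downsample_cell <- function(tensor, cell, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(tensor)
  obs_drugs <- tensor$drugs[tensor$observed[, cell]]
  keep_n <- round(fraction * length(obs_drugs))
  if (keep_n < 2L) {
    stop(sprintf(
      "fraction %.2f would leave %d < 2 observed drugs in '%s'",
      fraction, keep_n, cell))
  }
  keep <- with_seed(seed, sample(obs_drugs, keep_n))
  drop <- setdiff(obs_drugs, keep)
  tensor_unobserve(tensor, cbind(drop, cell))
}
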