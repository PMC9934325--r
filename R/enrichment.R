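#' Drug-set (perturbagen class) enrichment of a connectivity result
#'
#' Tests whether the members of a drug class cluster toward the top of a
#' ranked connectivity result, using the weighted-KS statistic over the
#' drug list with the connectivity scores as weights.  The query drug is
#' always removed both from the ranked list and from its own class.
#' Significance comes from permutations that shuffle class membership over
#' the list positions while keeping the score vector fixed; the normalized
#' score (NCS) mean-scales the observed ES by the absolute mean of the
#' same-sign permutation scores (a set-size-matched normalization group),
#' so a random placement has expected NCS near 0.  The p-value compares
#' magnitudes with the add-one rule,
#' `p = (1 + #\{|NCS_perm| >= |NCS_obs|\}) / (1 + B)`, so it is uniform
#' under the null and its minimum is `1/(1 + B)`, never 0.
#'
#' @param result a [query_connectivity()] result, or any data.frame with
#'   `drug` and a score column, or a named numeric score vector.
#' @param pcl_members character vector of the class's drug identifiers.
#' @param query_drug drug whose signature produced `result`; removed from
#'   the list and the set (`NULL` if not applicable).
#' @param n_permutations number of membership permutations (default 1000),
#'   or `"exhaustive"` to enumerate every `choose(n, m)` placement (only
#'   feasible for small lists; used by oracle tests).
#' @param seed integer seeding the permutations.
#' @param p weight exponent of the enrichment score.
#' @param score_col which score weights the KS walk when `result` is a
#'   connectivity result (default `"wcs"`).
#' @return A `drug_set_enrichment` list: `es`, `ncs`, `p_value`,
#'   `n_permutations`, `n_set`, `n_drugs`, `significant`
#'   (`ncs > 0 & p < 0.05`) and `perm_ncs` (the normalized permutation
#'   scores -- the null NCS sample, whose mean is ~0 by construction).
#'   Classes with fewer than 2 non-query members
#'   in the list raise a condition of class `conncf_set_too_small`.
#' @export
drug_set_enrichment <- function(result, pcl_members, query_drug = NULL,
                                n_permutations = 1000L, seed = 1L,
                                p = 1, score_col = "wcs") {
  if (is.data.frame(result)) {
    scores <- stats::setNames(result[[score_col]], result$drug)
  } else {
    scores <- result
  }
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)))
  if (!is.null(query_drug)) {
    scores <- scores[names(scores) != query_drug]
    pcl_members <- setdiff(pcl_members, query_drug)
  }
  members <- intersect(pcl_members, names(scores))
  if (length(members) < 2L) {
    conncf_error(sprintf(
      "drug set has %d member(s) in the result after removing the query drug; need >= 2",
      length(members)), "conncf_set_too_small")
  }
  n <- length(scores)
  m <- length(members)
  if (m >= n) {
    conncf_error("drug set covers the whole ranked list",
                 "conncf_set_too_small")
  }
  ord <- order(-scores, names(scores), method = "radix")
  z <- scores[ord]
  hit <- names(z) %in% members
  es_obs <- es_ranked(z, hit, p)

  if (identical(n_permutations, "exhaustive")) {
    placements <- combn(n, m)
    es_perm <- apply(placements, 2L, function(pos) {
      h <- logical(n); h[pos] <- TRUE
      es_ranked(z, h, p)
    })
  } else {
    es_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        h <- logical(n)
        h[sample.int(n, m)] <- TRUE
        es_ranked(z, h, p)
      }, numeric(1))
    })
  }
  b <- length(es_perm)
  mu_pos <- abs(mean(es_perm[es_perm > 0]))
  mu_neg <- abs(mean(es_perm[es_perm < 0]))
  norm1 <- function(x) {
    mu <- if (x > 0) mu_pos else if (x < 0) mu_neg else NA_real_
    if (is.na(mu) || mu == 0) {
      # degenerate group: fall back to the mean absolute permutation score
      mu <- mean(abs(es_perm))
      if (is.na(mu) || mu == 0) return(x)
    }
    x / mu
  }
  ncs_obs <- norm1(es_obs)
  ncs_perm <- vapply(es_perm, norm1, numeric(1))
  p_value <- if (ncs_obs == 0) 1 else {
    (1 + sum(abs(ncs_perm) >= abs(ncs_obs))) / (1 + b)
  }
  structure(list(es = es_obs, ncs = ncs_obs, p_value = p_value,
                 n_permutations = b, n_set = m, n_drugs = n,
                 significant = ncs_obs > 0 && p_value < 0.05,
                 perm_ncs = ncs_perm),
            class = "drug_set_enrichment")
}

#' @export
print.drug_set_enrichment <- function(x, ...) {
  cat(sprintf(
    "drug_set_enrichment: ES %.3f, NCS %.3f, p = %.4g (%d perms, set %d/%d)%s\n",
    x$es, x$ncs, x$p_value, x$n_permutations, x$n_set, x$n_drugs,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Perturbagen-class recovery over an imputed tensor
#'
#' For every drug in a usable class (at least `min_size` members on the
#' drug axis) and every requested cell: extract the top/bottom-k signature
#' from the *imputed* (drug, cell) profile, query the target tensor (the
#' true tensor by default, or the imputed one for fully-imputed-matrix
#' mode), and run [drug_set_enrichment()] with the drug's own class.  A
#' drug is *recovered* iff its NCS is positive and its permutation p-value
#' is below `alpha`.  Output is the recovery percentage per (class, cell).
#'
#' @param imputed_tensor tensor supplying the query signatures.
#' @param true_tensor tensor that is queried (set `mode = "imputed"` to
#'   query `imputed_tensor` itself).
#' @param pcl_catalog a [pcl_catalog()].
#' @param cells cells to evaluate (default: all cells of the true tensor).
#' @param signature_k per-side signature size (default 50, capped at half
#'   the gene axis).
#' @param n_permutations,seed,p passed to [drug_set_enrichment()].
#' @param alpha significance threshold (default 0.05).
#' @param mode `"true"` (query the true tensor) or `"imputed"`.
#' @return List with `summary` (data.frame: pcl, cell, n_drugs, n_recovered,
#'   pct_recovered), `detail` (per drug/cell/pcl: ncs, p_value,
#'   significant) and `skipped` (unusable classes or skipped queries with
#'   reasons).
#' @export
pcl_recovery_matrix <- function(imputed_tensor, true_tensor, pcl_catalog,
                                cells = NULL, signature_k = 50L,
                                n_permutations = 1000L, seed = 1L, p = 1,
                                alpha = 0.05,
                                mode = c("true", "imputed")) {
  mode <- match.arg(mode)
  target <- if (mode == "true") true_tensor else imputed_tensor
  if (is.null(cells)) cells <- target$cells
  signature_k <- min(signature_k, floor(length(imputed_tensor$genes) / 2))
  usable <- usable_classes(pcl_catalog, imputed_tensor$drugs)
  skipped <- lapply(
    setdiff(names(pcl_catalog$classes), names(usable)),
    function(nm) data.frame(pcl = nm, cell = NA_character_,
                            drug = NA_character_,
                            reason = sprintf("class has < %d members on the drug axis",
                                             pcl_catalog$min_size),
                            stringsAsFactors = FALSE))
  detail <- list()
  qseed <- seed
  for (pcl in names(usable)) {
    for (cl in cells) {
      for (d in usable[[pcl]]) {
        if (!imputed_tensor$observed[d, cl]) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            pcl = pcl, cell = cl, drug = d,
            reason = "no imputed profile for this pair",
            stringsAsFactors = FALSE)
          next
        }
        sig <- extract_signature(imputed_tensor$values[d, cl, ],
                                 k = signature_k)
        res <- query_connectivity(target, cl, sig, polarity = "positive",
                                  p = p)
        qseed <- (qseed + 9973L) %% 2147483647L
        enr <- tryCatch(
          drug_set_enrichment(res, usable[[pcl]], query_drug = d,
                              n_permutations = n_permutations,
                              seed = qseed, p = p),
          conncf_set_too_small = function(e) e)
        if (inherits(enr, "conncf_set_too_small")) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            pcl = pcl, cell = cl, drug = d,
            reason = conditionMessage(enr), stringsAsFactors = FALSE)
          next
        }
        detail[[length(detail) + 1L]] <- data.frame(
          drug = d, cell = cl, pcl = pcl, ncs = enr$ncs,
          p_value = enr$p_value,
          significant = enr$ncs > 0 && enr$p_value < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- if (length(detail) > 0L) do.call(rbind, detail) else
    data.frame(drug = character(), cell = character(), pcl = character(),
               ncs = numeric(), p_value = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  skipped <- if (length(skipped) > 0L) do.call(rbind, skipped) else
    data.frame(pcl = character(), cell = character(), drug = character(),
               reason = character(), stringsAsFactors = FALSE)
  summary <- if (nrow(detail) > 0L) {
    agg <- aggregate(significant ~ pcl + cell, detail,
                     function(x) c(n = length(x), rec = sum(x)))
    data.frame(pcl = agg$pcl, cell = agg$cell,
               n_drugs = agg$significant[, "n"],
               n_recovered = agg$significant[, "rec"],
               pct_recovered = 100 * agg$significant[, "rec"] /
                 agg$significant[, "n"],
               stringsAsFactors = FALSE)
  } else {
    data.frame(pcl = character(), cell = character(), n_drugs = integer(),
               n_recovered = integer(), pct_recovered = numeric(),
               stringsAsFactors = FALSE)
  }
  list(summary = summary, detail = detail, skipped = skipped)
}
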