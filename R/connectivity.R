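#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Ranks the profile by descending z-score (ties broken by gene identifier)
#' and walks the list accumulating a running sum: a *hit* (gene in the set)
#' adds `|z|^p / N_R` where `N_R` is the sum of `|z|^p` over set members; a
#' *miss* subtracts `1/(N - N_set)`.  The ES is the running sum at its
#' maximum absolute deviation from zero, keeping sign, and lies in \[-1, 1\].
#' With `p = 0` this is the classical (unweighted) two-sample KS statistic.
#'
#' @param profile named numeric z-score vector (the reference profile); no
#'   duplicate names.
#' @param gene_set character vector of gene identifiers; must be a
#'   non-empty proper subset of the profile's genes.
#' @param p nonnegative weight exponent (default 1, the weighted-KS default
#'   of gene-set enrichment analysis).
#' @return The signed enrichment score, a scalar in \[-1, 1\].
#' @examples
#' z <- c(a = 4, b = 3, c = 2, d = 1)
#' enrichment_score(z, "a")   #  1.0: the set sits at the very top
#' enrichment_score(z, "d")   # -1.0: maximal deviation before the hit
#' @export
enrichment_score <- function(profile, gene_set, p = 1) {
  stopifnot(!is.null(names(profile)), !anyDuplicated(names(profile)))
  gene_set <- unique(as.character(gene_set))
  missing <- setdiff(gene_set, names(profile))
  if (length(missing) > 0L) {
    stop(sprintf("gene set members absent from profile: %s",
                 paste(missing, collapse = ", ")))
  }
  ord <- order(-profile, names(profile), method = "radix")
  es_ranked(profile[ord], names(profile)[ord] %in% gene_set, p)
}

# Core running sum on an already-ranked profile. `member` is the logical
# hit indicator aligned with `z` (descending order).
es_ranked <- function(z, member, p) {
  n <- length(z)
  ns <- sum(member)
  if (ns == 0L) stop("gene set has no members in the profile")
  if (ns >= n) stop("gene set equal to the whole universe: miss denominator is zero")
  w <- abs(z)^p
  w[!member] <- 0
  nr <- sum(w)
  hit <- if (nr > 0) w / nr else member / ns  # all-zero scores: unweighted
  run <- cumsum(hit - (!member) / (n - ns))
  unname(run[which.max(abs(run))])
}

#' Weighted connectivity score of a signature against one profile
#'
#' Computes `ES_up` for the signature's up set and `ES_down` for its down
#' set against the profile ranked by descending z-score, then
#' `WCS = (ES_up - ES_down) / 2` when the two enrichment scores have
#' opposite signs, and 0 otherwise.  WCS lies in \[-1, 1\]; +1 means the
#' profile reproduces the query signature, -1 that it reverses it.
#'
#' @param profile named numeric z-score vector.
#' @param signature a [query_signature()]; both sets must be subsets of the
#'   profile's genes (absent genes are an error, never silently dropped).
#' @param p weight exponent passed to the enrichment score.
#' @return Named numeric vector `c(es_up, es_down, wcs)`.
#' @export
weighted_connectivity_score <- function(profile, signature, p = 1) {
  stopifnot(inherits(signature, "query_signature"))
  missing <- setdiff(c(signature$up, signature$down), names(profile))
  if (length(missing) > 0L) {
    stop(sprintf("signature genes absent from profile: %s",
                 paste(missing, collapse = ", ")))
  }
  ord <- order(-profile, names(profile), method = "radix")
  z <- profile[ord]
  nm <- names(profile)[ord]
  es_up <- es_ranked(z, nm %in% signature$up, p)
  es_down <- es_ranked(z, nm %in% signature$down, p)
  wcs <- if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
  c(es_up = es_up, es_down = es_down, wcs = wcs)
}

#' Normalize connectivity scores within per-cell groups
#'
#' Mean-scales WCS values so that they are comparable across cells: within
#' each group (one cell's scores for one query), positive scores are
#' divided by the absolute mean of the group's positive scores and negative
#' scores by the absolute mean of its negative scores.  After scaling, the
#' mean of positive NCS is exactly +1 and of negative NCS exactly -1
#' wherever both signs occur.  Degenerate groups: a sign that never occurs
#' needs no normalizer; if a group's same-sign mean is exactly 0 (all-zero
#' scores) the NCS is 0.
#'
#' @param scores data.frame with columns `cell`, `drug`, `wcs` (one query's
#'   results, possibly over several cells).
#' @return The input with an `ncs` column appended.
#' @export
normalize_scores <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("cell", "drug", "wcs") %in% names(scores)))
  ncs <- numeric(nrow(scores))
  for (cl in unique(scores$cell)) {
    i <- scores$cell == cl
    w <- scores$wcs[i]
    mu_pos <- abs(mean(w[w > 0]))
    mu_neg <- abs(mean(w[w < 0]))
    s <- numeric(length(w))
    pos <- w > 0; neg <- w < 0
    if (any(pos)) s[pos] <- if (mu_pos > 0) w[pos] / mu_pos else 0
    if (any(neg)) s[neg] <- if (mu_neg > 0) w[neg] / mu_neg else 0
    ncs[i] <- s
  }
  scores$ncs <- ncs
  scores
}

#' Run a ranked connectivity query against one cell
#'
#' Scores the signature against the profile of every drug observed in the
#' given cell and returns the drugs ranked by WCS: descending for
#' `polarity = "positive"` (drugs mimicking the query first), ascending for
#' `"negative"` (drugs reversing it first).  NCS is computed over the
#' result set (the per-cell normalization group).  Ties in WCS keep a
#' stable order by drug identifier.
#'
#' @param tensor an `expression_tensor` (true or imputed).
#' @param cell cell identifier; at least one drug must be observed there.
#' @param signature a [query_signature()]; all its genes must be on the
#'   tensor's gene axis.
#' @param polarity `"positive"` or `"negative"`.
#' @param p weight exponent.
#' @return A `connectivity_result`: data.frame with columns `drug`,
#'   `es_up`, `es_down`, `wcs`, `ncs`, `rank`, plus attributes `cell`,
#'   `polarity` and `signature`.
#' @export
query_connectivity <- function(tensor, cell, signature,
                               polarity = c("positive", "negative"),
                               p = 1) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(signature, "query_signature"))
  if (!cell %in% tensor$cells) stop(sprintf("unknown cell '%s'", cell))
  missing <- setdiff(c(signature$up, signature$down), tensor$genes)
  if (length(missing) > 0L) {
    stop(sprintf("signature genes absent from gene axis: %s",
                 paste(missing, collapse = ", ")))
  }
  drugs <- tensor$drugs[tensor$observed[, cell]]
  if (length(drugs) == 0L) {
    stop(sprintf("cell '%s' has no observed profiles", cell))
  }
  sc <- vapply(drugs, function(d) {
    weighted_connectivity_score(tensor$values[d, cell, ], signature, p)
  }, c(es_up = 0, es_down = 0, wcs = 0))
  res <- data.frame(drug = drugs, es_up = sc["es_up", ],
                    es_down = sc["es_down", ], wcs = sc["wcs", ],
                    cell = cell, stringsAsFactors = FALSE,
                    row.names = NULL)
  res <- normalize_scores(res)[, c("drug", "es_up", "es_down", "wcs",
                                   "ncs")]
  ord <- if (polarity == "positive") {
    order(-res$wcs, res$drug, method = "radix")
  } else {
    order(res$wcs, res$drug, method = "radix")
  }
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res, cell = cell, polarity = polarity, signature = signature,
            class = c("connectivity_result", "data.frame"))
}
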