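#' Parameters for neighborhood collaborative filtering
#'
#' @param k_neighbors number of neighbor drugs to average.  The field
#'   default is a round number near ten percent of the drug axis (50 for a
#'   450-drug matrix, 120 for 1330 drugs); when `NULL`, `ceil(0.10 *
#'   n_drugs)` is used at imputation time.
#' @param min_overlap minimum number of co-observed columns required before
#'   an adjusted-cosine similarity between two drugs is considered defined
#'   (default 10; cosines over tiny overlaps are noise).
#' @param exclude_negative drop negatively-similar drugs from the
#'   neighborhood instead of letting them contribute with negative weight
#'   (default `FALSE`: top-k by signed similarity).
#' @return An `ncf_params` list.
#' @export
ncf_params <- function(k_neighbors = NULL, min_overlap = 10L,
                       exclude_negative = FALSE) {
  stopifnot(is.null(k_neighbors) || k_neighbors >= 1L, min_overlap >= 1L)
  structure(list(k_neighbors = k_neighbors,
                 min_overlap = as.integer(min_overlap),
                 exclude_negative = isTRUE(exclude_negative)),
            class = "ncf_params")
}

#' Tissue-agnostic imputation
#'
#' Predicts the profile of `drug` in `cell` as, per gene, the median of
#' that drug's z-scores over all *other* cells in which it was assayed --
#' "what the drug usually does", ignoring cell identity.  This mirrors the
#' cross-cell summary used by classical connectivity tools and serves as
#' the baseline every cell-aware method is compared against.
#'
#' @param tensor an `expression_tensor`.
#' @param drug,cell target pair; the drug must be observed in at least one
#'   cell other than `cell`.
#' @return Named numeric vector over the gene axis.
#' @export
impute_tissue_agnostic <- function(tensor, drug, cell) {
  other <- setdiff(tensor$cells[tensor$observed[drug, ]], cell)
  if (length(other) == 0L) {
    conncf_error(sprintf(
      "drug '%s' is observed in no cell other than '%s'", drug, cell),
      "conncf_no_data")
  }
  block <- tensor$values[drug, other, , drop = FALSE]
  apply(block, 3L, median)
}

#' Median-of-medians imputation
#'
#' Per gene, averages two medians: the drug's median over all other cells
#' (the tissue-agnostic prediction) and the cell's median over all other
#' drugs (a "drug-agnostic" profile of how this cell typically responds).
#' The median of two values is their mean, so this blends drug identity and
#' cell identity with equal weight.
#'
#' @inheritParams impute_tissue_agnostic
#' @return Named numeric vector over the gene axis.
#' @export
impute_mom <- function(tensor, drug, cell) {
  row_med <- impute_tissue_agnostic(tensor, drug, cell)
  other_drugs <- setdiff(tensor$drugs[tensor$observed[, cell]], drug)
  if (length(other_drugs) == 0L) {
    conncf_error(sprintf(
      "cell '%s' is observed for no drug other than '%s'", cell, drug),
      "conncf_no_data")
  }
  block <- tensor$values[other_drugs, cell, , drop = FALSE]
  col_med <- apply(block, 3L, median)
  (row_med + col_med) / 2
}

#' Adjusted-cosine similarity between drugs
#'
#' Mean-centers every row of the reshaped matrix over its observed entries,
#' then takes the cosine of each pair of centered rows restricted to their
#' co-observed columns.  Pairs with fewer than `min_overlap` co-observed
#' columns (or a zero norm) are `NA`.  The matrix is symmetric with unit
#' diagonal where defined and entries in \[-1, 1\].
#'
#' @param R a [reshape_tensor()] result.
#' @param min_overlap minimum co-observed columns (default 10).
#' @param exclude_cell optional cell identifier whose column block is
#'   dropped before computing similarities -- used during imputation so the
#'   target cell's data never informs neighbor choice.
#' @return drugs-by-drugs numeric matrix.
#' @export
drug_similarity <- function(R, min_overlap = 10L, exclude_cell = NULL) {
  stopifnot(inherits(R, "reshaped_matrix"))
  x <- R$values
  if (!is.null(exclude_cell)) x <- x[, -cell_block(R, exclude_cell),
                                     drop = FALSE]
  if (nrow(x) < 2L) stop("need at least two drugs")
  mask <- !is.na(x)
  n_obs <- rowSums(mask)
  rc <- ifelse(n_obs > 0L, rowSums(x, na.rm = TRUE) / pmax(n_obs, 1L), 0)
  xc <- x - rc
  xc[!mask] <- 0
  storage.mode(mask) <- "double"
  num <- tcrossprod(xc)
  a <- tcrossprod(xc^2, mask)      # a[i,j] = ||xc_i||^2 over cols observed in j
  overlap <- tcrossprod(mask)
  denom <- sqrt(a * t(a))
  sim <- num / denom
  sim[denom == 0 | overlap < min_overlap] <- NA_real_
  sim[!is.na(sim)] <- pmin(1, pmax(-1, sim[!is.na(sim)]))  # fp guard
  dimnames(sim) <- list(R$drugs, R$drugs)
  sim
}

#' Neighborhood collaborative filtering imputation
#'
#' Imputes the profile of `drug` in `cell` from the profiles, *in that
#' cell*, of the drugs most similar to it.  Similarity is the adjusted
#' cosine over the reshaped matrix with the target cell's column block
#' excluded (so the withheld data cannot leak into neighbor selection).
#' Eligible neighbors are other drugs with a defined similarity that were
#' assayed in the target cell; the top `k` by signed similarity are
#' averaged per gene with weights `sim / sum(|sim|)`.
#'
#' @param R a [reshape_tensor()] result built from the *training* data.
#' @param drug,cell target pair.
#' @param params an [ncf_params()] object.
#' @param similarities optional precomputed [drug_similarity()] matrix for
#'   this target cell (must have been computed with `exclude_cell = cell`);
#'   recomputed when `NULL`.
#' @return Named numeric vector over the gene axis, with attribute
#'   `neighbors` (data.frame of the drugs used and their similarities).
#' @export
impute_ncf <- function(R, drug, cell, params = ncf_params(),
                       similarities = NULL) {
  stopifnot(inherits(R, "reshaped_matrix"))
  if (is.null(similarities)) {
    similarities <- drug_similarity(R, min_overlap = params$min_overlap,
                                    exclude_cell = cell)
  }
  s <- similarities[drug, ]
  s <- s[names(s) != drug]
  in_cell <- R$observed[names(s), cell]
  s <- s[!is.na(s) & in_cell]
  if (params$exclude_negative) s <- s[s > 0]
  if (length(s) == 0L) {
    conncf_error(sprintf(
      "no eligible neighbor for (%s, %s): need a drug observed in '%s' with a defined similarity",
      drug, cell, cell), "conncf_no_neighbors")
  }
  k <- params$k_neighbors
  if (is.null(k)) k <- ceiling(0.10 * length(R$drugs))
  sel <- names(s)[order(-s, names(s), method = "radix")]
  sel <- sel[seq_len(min(k, length(sel)))]
  w <- s[sel]
  if (sum(abs(w)) == 0) {
    conncf_error(sprintf(
      "neighbor similarities for (%s, %s) sum to zero in absolute value",
      drug, cell), "conncf_no_neighbors")
  }
  vals <- R$values[sel, cell_block(R, cell), drop = FALSE]
  pred <- colSums(vals * w) / sum(abs(w))
  names(pred) <- R$genes
  attr(pred, "neighbors") <- data.frame(drug = sel, similarity = unname(w),
                                        stringsAsFactors = FALSE)
  pred
}
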