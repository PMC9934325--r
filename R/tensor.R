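#' Construct an expression tensor
#'
#' An `expression_tensor` holds differential-expression z-scores indexed by
#' (drug, cell, gene), with *all-or-nothing* missingness per (drug, cell)
#' pair: a pair either carries a z-score for every gene (observed) or none
#' at all.  Values are stored in a dense 3-d array with `NA` filling
#' unobserved blocks, alongside an explicit drug-by-cell `observed` mask, so
#' that `0` (and even a stray `NA`-free block) is never overloaded as a
#' missingness sentinel.
#'
#' @param values numeric array of dimension (drugs, cells, genes).
#'   Unobserved (drug, cell) blocks must be all-`NA`.
#' @param drugs,cells,genes character vectors of unique axis identifiers.
#'   Defaults are taken from `dimnames(values)`.
#' @param observed logical drug-by-cell matrix; if `NULL`, inferred from the
#'   `NA` pattern of `values` (a block observed iff its first gene is
#'   non-`NA`, then validated).
#' @return An object of class `expression_tensor`: a list with elements
#'   `drugs`, `cells`, `genes`, `values` (3-d array) and `observed`
#'   (logical matrix).
#' @examples
#' v <- array(rnorm(2 * 2 * 3), c(2, 2, 3),
#'            dimnames = list(c("d1", "d2"), c("c1", "c2"),
#'                            c("g1", "g2", "g3")))
#' v["d2", "c1", ] <- NA          # unassayed pair
#' tens <- expression_tensor(v)
#' tensor_observed(tens)
#' @export
expression_tensor <- function(values, drugs = NULL, cells = NULL,
                              genes = NULL, observed = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  dn <- dimnames(values)
  if (is.null(drugs)) drugs <- dn[[1L]]
  if (is.null(cells)) cells <- dn[[2L]]
  if (is.null(genes)) genes <- dn[[3L]]
  if (is.null(drugs) || is.null(cells) || is.null(genes)) {
    stop("axis identifiers must be supplied or present as dimnames")
  }
  drugs <- as.character(drugs); cells <- as.character(cells)
  genes <- as.character(genes)
  if (anyDuplicated(drugs) || anyDuplicated(cells) || anyDuplicated(genes)) {
    stop("axis identifiers must be unique within each axis")
  }
  stopifnot(dim(values)[1L] == length(drugs),
            dim(values)[2L] == length(cells),
            dim(values)[3L] == length(genes))
  dimnames(values) <- list(drugs, cells, genes)
  storage.mode(values) <- "double"
  if (is.null(observed)) {
    observed <- !is.na(values[, , 1L, drop = FALSE])[, , 1L, drop = TRUE]
    observed <- matrix(observed, length(drugs), length(cells),
                       dimnames = list(drugs, cells))
  } else {
    observed <- matrix(as.logical(observed), length(drugs), length(cells),
                       dimnames = list(drugs, cells))
  }
  x <- structure(list(drugs = drugs, cells = cells, genes = genes,
                      values = values, observed = observed),
                 class = "expression_tensor")
  validate_tensor(x)
  x
}

validate_tensor <- function(x) {
  nas <- is.na(x$values)
  for (j in seq_along(x$cells)) {
    block_na <- nas[, j, , drop = FALSE]
    n_na <- rowSums(block_na, dims = 1L)
    bad_obs <- x$observed[, j] & n_na > 0L
    bad_mis <- !x$observed[, j] & n_na < length(x$genes)
    if (any(bad_obs) || any(bad_mis)) {
      d <- x$drugs[which(bad_obs | bad_mis)[1L]]
      stop(sprintf(
        "all-or-nothing violation for pair (%s, %s): %s", d, x$cells[j],
        if (any(bad_obs)) "observed block contains NA"
        else "unobserved block contains values"))
    }
  }
  invisible(x)
}

#' @export
print.expression_tensor <- function(x, ...) {
  n_obs <- sum(x$observed)
  cat(sprintf(
    "expression_tensor: %d drugs x %d cells x %d genes; %d/%d pairs observed (%.1f%%)\n",
    length(x$drugs), length(x$cells), length(x$genes),
    n_obs, length(x$observed), 100 * n_obs / length(x$observed)))
  invisible(x)
}

#' Tensor accessors
#'
#' `tensor_profile()` returns the per-gene z-score vector of one observed
#' (drug, cell) pair; `tensor_observed()` the drug-by-cell logical mask;
#' `tensor_set_profile()` writes a profile (marking the pair observed);
#' `tensor_unobserve()` blanks pairs back to missing.
#'
#' @param x an `expression_tensor`.
#' @param drug,cell axis identifiers.
#' @param profile named numeric vector over the tensor's gene axis.
#' @param pairs two-column matrix or data.frame of (drug, cell) identifiers.
#' @return `tensor_profile()`: a named numeric vector; `tensor_observed()`:
#'   a logical matrix; the setters return the modified tensor.
#' @export
tensor_profile <- function(x, drug, cell) {
  if (!x$observed[drug, cell]) {
    stop(sprintf("pair (%s, %s) is not observed", drug, cell))
  }
  x$values[drug, cell, ]
}

#' @rdname tensor_profile
#' @export
tensor_observed <- function(x) x$observed

#' @rdname tensor_profile
#' @export
tensor_set_profile <- function(x, drug, cell, profile) {
  stopifnot(length(profile) == length(x$genes), !anyNA(profile))
  if (!is.null(names(profile))) profile <- profile[x$genes]
  x$values[drug, cell, ] <- profile
  x$observed[drug, cell] <- TRUE
  x
}

#' @rdname tensor_profile
#' @export
tensor_unobserve <- function(x, pairs) {
  pairs <- as.matrix(pairs)
  for (r in seq_len(nrow(pairs))) {
    x$values[pairs[r, 1L], pairs[r, 2L], ] <- NA_real_
    x$observed[pairs[r, 1L], pairs[r, 2L]] <- FALSE
  }
  x
}

#' Compare two tensors for equality of axes, mask and observed values
#'
#' Axis *order* may differ; values are compared by identifier.
#'
#' @param a,b `expression_tensor` objects.
#' @param tol absolute tolerance on observed values (0 for exact).
#' @return `TRUE` or `FALSE`.
#' @export
tensor_equal <- function(a, b, tol = 0) {
  if (!setequal(a$drugs, b$drugs) || !setequal(a$cells, b$cells) ||
      !setequal(a$genes, b$genes)) {
    return(FALSE)
  }
  bo <- b$observed[a$drugs, a$cells, drop = FALSE]
  if (!identical(unname(a$observed), unname(bo))) return(FALSE)
  bv <- b$values[a$drugs, a$cells, b$genes, drop = FALSE][, , a$genes,
                                                          drop = FALSE]
  av <- a$values
  ok <- is.na(av) == is.na(bv)
  if (!all(ok)) return(FALSE)
  d <- abs(av - bv)
  all(d[!is.na(d)] <= tol)
}

#' Reshape a tensor into the drugs-by-(cells x genes) matrix R
#'
#' Rows are drugs; columns concatenate, cell by cell, the full gene axis
#' (all genes of the first cell, then all genes of the second cell, ...).
#' This is the 2-d view consumed by collaborative filtering and Funk SVD.
#' Unobserved (drug, cell) blocks are `NA` in `values` and carried in the
#' explicit `observed` mask, so the reshape is exactly invertible.
#'
#' @param tensor an `expression_tensor`.
#' @return A `reshaped_matrix`: list with `values` (drugs x (cells*genes)
#'   matrix, column names `"cell:gene"`), `observed` (drug-by-cell mask) and
#'   the three axis vectors.
#' @seealso [unreshape_matrix()] for the inverse.
#' @export
reshape_tensor <- function(tensor) {
  nd <- length(tensor$drugs); nc <- length(tensor$cells)
  ng <- length(tensor$genes)
  # aperm to (drug, gene, cell) then flatten gene-within-cell
  vals <- matrix(aperm(tensor$values, c(1L, 3L, 2L)), nrow = nd,
                 ncol = nc * ng)
  dimnames(vals) <- list(tensor$drugs,
                         paste(rep(tensor$cells, each = ng),
                               rep(tensor$genes, times = nc), sep = ":"))
  structure(list(values = vals, observed = tensor$observed,
                 drugs = tensor$drugs, cells = tensor$cells,
                 genes = tensor$genes),
            class = "reshaped_matrix")
}

#' Invert [reshape_tensor()]
#'
#' @param R a `reshaped_matrix`.
#' @return The `expression_tensor` whose reshape is `R`; bit-exact on every
#'   observed value.
#' @export
unreshape_matrix <- function(R) {
  nd <- length(R$drugs); nc <- length(R$cells); ng <- length(R$genes)
  arr <- aperm(array(R$values, c(nd, ng, nc)), c(1L, 3L, 2L))
  dimnames(arr) <- list(R$drugs, R$cells, R$genes)
  expression_tensor(arr, observed = R$observed)
}

#' @export
print.reshaped_matrix <- function(x, ...) {
  cat(sprintf("reshaped_matrix: %d drugs x %d columns (%d cells x %d genes)\n",
              length(x$drugs), ncol(x$values), length(x$cells),
              length(x$genes)))
  invisible(x)
}

# Column indices of one cell's block in the reshaped matrix.
cell_block <- function(R, cell) {
  j <- match(cell, R$cells)
  if (is.na(j)) stop(sprintf("unknown cell '%s'", cell))
  ng <- length(R$genes)
  seq.int((j - 1L) * ng + 1L, j * ng)
}
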