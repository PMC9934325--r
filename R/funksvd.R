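#' Parameters for Funk-SVD matrix factorization
#'
#' @param rank number of latent factors (field setting for a 1330-drug
#'   LINCS-like matrix: 55; must not exceed either matrix dimension).
#' @param learning_rate SGD step size (default 0.001, Funk's published
#'   Netflix setting).
#' @param regularization L2 penalty on both factor matrices (default
#'   0.015, ditto).
#' @param max_epochs maximum passes over the observed entries (default
#'   200).
#' @param tol stop when the epoch-to-epoch training-RMSE improvement falls
#'   below this (default 1e-4).
#' @param seed integer seeding the factor initialization (uniform on
#'   `[-init_range, init_range]`) and the per-epoch shuffles; fits are
#'   bit-reproducible given the seed.
#' @param init_range half-width of the uniform initialization (default
#'   0.05).
#' @return An `svd_params` list.
#' @export
svd_params <- function(rank = 55L, learning_rate = 0.001,
                       regularization = 0.015, max_epochs = 200L,
                       tol = 1e-4, seed = 1L, init_range = 0.05) {
  stopifnot(rank >= 1L, learning_rate > 0, regularization >= 0,
            max_epochs >= 1L, tol >= 0, init_range > 0)
  structure(list(rank = as.integer(rank), learning_rate = learning_rate,
                 regularization = regularization,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 seed = as.integer(seed), init_range = init_range),
            class = "svd_params")
}

#' Fit a Funk-SVD factorization of the reshaped matrix
#'
#' Minimizes squared error over the *observed* entries only (missing blocks
#' are simply never visited, so no fill-in guess is required), with L2
#' regularization, by stochastic gradient descent in a seeded shuffled
#' order.  Training stops when the epoch RMSE improves by less than `tol`
#' or after `max_epochs`; non-finite RMSE aborts with advice to lower the
#' learning rate.
#'
#' @param R a [reshape_tensor()] result (training data).
#' @param params an [svd_params()] object; `rank` must be at most
#'   `min(dim)` of the matrix.
#' @return A `funk_svd_fit`: list with `U` (drugs x rank), `V`
#'   (columns x rank), `rmse_trace`, `params`, and the axis vectors needed
#'   by [funk_svd_predict()].
#' @export
funk_svd_fit <- function(R, params = svd_params()) {
  stopifnot(inherits(R, "reshaped_matrix"), inherits(params, "svd_params"))
  if (params$rank > min(dim(R$values))) {
    stop("rank exceeds min(rows, cols) of the reshaped matrix")
  }
  # expand drug-by-cell mask to drug-by-(cell*gene) columns
  ng <- length(R$genes)
  obs <- R$observed[, rep(seq_along(R$cells), each = ng), drop = FALSE]
  fit <- funk_svd_sgd(R$values, obs, params$rank, params$learning_rate,
                      params$regularization, params$max_epochs,
                      params$tol, params$seed, params$init_range)
  rownames(fit$U) <- R$drugs
  rownames(fit$V) <- colnames(R$values)
  structure(list(U = fit$U, V = fit$V, rmse_trace = fit$rmse_trace,
                 params = params, drugs = R$drugs, cells = R$cells,
                 genes = R$genes),
            class = "funk_svd_fit")
}

#' @export
print.funk_svd_fit <- function(x, ...) {
  cat(sprintf(
    "funk_svd_fit: rank %d, %d drugs x %d columns; %d epochs, final RMSE %.4g\n",
    x$params$rank, nrow(x$U), nrow(x$V), length(x$rmse_trace),
    x$rmse_trace[length(x$rmse_trace)]))
  invisible(x)
}

#' Predict one (drug, cell) profile from a Funk-SVD fit
#'
#' Takes the slice of the low-rank reconstruction `U V'` corresponding to
#' the target cell's column block.
#'
#' @param fit a [funk_svd_fit()] result.
#' @param drug,cell target pair; the drug must be a row of the fit.
#' @return Named numeric vector over the gene axis.
#' @export
funk_svd_predict <- function(fit, drug, cell) {
  stopifnot(inherits(fit, "funk_svd_fit"))
  i <- match(drug, fit$drugs)
  if (is.na(i)) stop(sprintf("unknown drug '%s'", drug))
  j <- match(cell, fit$cells)
  if (is.na(j)) stop(sprintf("unknown cell '%s'", cell))
  ng <- length(fit$genes)
  cols <- seq.int((j - 1L) * ng + 1L, j * ng)
  pred <- as.numeric(fit$V[cols, , drop = FALSE] %*% fit$U[i, ])
  names(pred) <- fit$genes
  pred
}
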