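#' Construct a query signature
#'
#' A query signature is a pair of disjoint gene sets: the most up-regulated
#' (`up`, often written S+) and most down-regulated (`down`, S-) genes of a
#' comparison.
#'
#' @param up,down character vectors of gene identifiers; must be disjoint
#'   and non-empty.
#' @param k nominal per-side size; defaults to `max(length(up),
#'   length(down))`.
#' @return A `query_signature` (list with `up`, `down`, `k`).
#' @export
query_signature <- function(up, down, k = NULL) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(up) == 0L || length(down) == 0L) {
    stop("both up and down sets must be non-empty")
  }
  if (length(intersect(up, down)) > 0L) {
    stop("up and down sets must be disjoint")
  }
  if (is.null(k)) k <- max(length(up), length(down))
  stopifnot(length(up) <= k, length(down) <= k)
  structure(list(up = up, down = down, k = as.integer(k)),
            class = "query_signature")
}

#' @export
print.query_signature <- function(x, ...) {
  cat(sprintf("query_signature: %d up / %d down genes (k = %d)\n",
              length(x$up), length(x$down), x$k))
  invisible(x)
}

#' Extract the top/bottom-k signature of an expression profile
#'
#' Returns the `k` genes with the largest z-scores (`up`) and the `k` with
#' the smallest (`down`).  Ties at the k-th boundary are broken
#' deterministically: among tied z-scores the lexicographically smaller
#' gene identifier wins the last slot, so results are platform-independent.
#' Connectivity practice uses k = 50 per side.
#'
#' @param profile named numeric vector of z-scores (names = genes).
#' @param k per-side signature size; `profile` must contain at least `2k`
#'   finite values.
#' @return A `query_signature`.
#' @examples
#' extract_signature(c(g1 = 3, g2 = 1, g3 = -1, g4 = -3), k = 1)
#' @export
extract_signature <- function(profile, k = 50L) {
  stopifnot(!is.null(names(profile)), k >= 1L)
  profile <- profile[is.finite(profile)]
  if (length(profile) < 2L * k) {
    stop(sprintf("need at least 2k = %d finite genes, have %d",
                 2L * k, length(profile)))
  }
  ord_desc <- order(-profile, names(profile), method = "radix")
  ord_asc <- order(profile, names(profile), method = "radix")
  query_signature(up = names(profile)[ord_desc[seq_len(k)]],
                  down = names(profile)[ord_asc[seq_len(k)]],
                  k = k)
}
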