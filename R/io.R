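#' Read and write expression tensors
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`"long"`}{tab-separated with header `drug  cell  gene  zscore`,
#'     one row per observed (drug, cell, gene) value.  Unobserved pairs are
#'     simply absent.  Ragged pairs (a (drug, cell) pair carrying only part
#'     of the gene axis) and duplicate (drug, cell, gene) rows are errors.}
#'   \item{`"gct"`}{GCT 1.3 text.  Genes are rows; each observed (drug,
#'     cell) pair is one column labelled `"<drug>:<cell>"`.  On read, a
#'     column that is entirely `NA` is treated as an unobserved pair;
#'     a partially-`NA` column violates all-or-nothing and is an error.}
#' }
#' Axis order on read follows first appearance in the file; observed values
#' round-trip exactly in both formats.
#'
#' @param path file path.
#' @param format `"long"` or `"gct"`; for `read_tensor` the default
#'   `"auto"` sniffs the `#1.3` magic line.
#' @param tensor an `expression_tensor`.
#' @return `read_tensor()` returns an `expression_tensor`; `write_tensor()`
#'   invisibly returns `path`.
#' @export
read_tensor <- function(path, format = c("auto", "long", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "#1.")) "gct" else "long"
  }
  switch(format, long = read_tensor_long(path), gct = read_tensor_gct(path))
}

#' @rdname read_tensor
#' @export
write_tensor <- function(tensor, path, format = c("long", "gct")) {
  format <- match.arg(format)
  switch(format,
         long = write_tensor_long(tensor, path),
         gct = write_tensor_gct(tensor, path))
  invisible(path)
}

read_tensor_long <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "character",
                                  "numeric"),
                   quote = "", comment.char = "")
  if (!all(c("drug", "cell", "gene", "zscore") %in% names(df))) {
    stop("long-TSV must have columns drug, cell, gene, zscore")
  }
  tensor_from_long(df)
}

tensor_from_long <- function(df) {
  drugs <- unique(df$drug); cells <- unique(df$cell)
  genes <- unique(df$gene)
  key <- paste(df$drug, df$cell, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate rows for (%s, %s, %s)", dup$drug, dup$cell,
                 dup$gene))
  }
  pair <- paste(df$drug, df$cell, sep = "\r")
  counts <- table(pair)
  if (any(counts != length(genes))) {
    bad <- names(counts)[counts != length(genes)][1L]
    bad <- strsplit(bad, "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "ragged gene set for pair (%s, %s): all-or-nothing violated",
      bad[1L], bad[2L]))
  }
  arr <- array(NA_real_, c(length(drugs), length(cells), length(genes)),
               dimnames = list(drugs, cells, genes))
  arr[cbind(match(df$drug, drugs), match(df$cell, cells),
            match(df$gene, genes))] <- df$zscore
  expression_tensor(arr)
}

write_tensor_long <- function(tensor, path) {
  obs <- which(tensor$observed, arr.ind = TRUE)
  obs <- obs[order(obs[, 1L], obs[, 2L]), , drop = FALSE]
  ng <- length(tensor$genes)
  n <- nrow(obs) * ng
  df <- data.frame(
    drug = rep(tensor$drugs[obs[, 1L]], each = ng),
    cell = rep(tensor$cells[obs[, 2L]], each = ng),
    gene = rep(tensor$genes, times = nrow(obs)),
    zscore = sprintf("%.17g",
                     tensor$values[cbind(rep(obs[, 1L], each = ng),
                                         rep(obs[, 2L], each = ng),
                                         rep(seq_len(ng),
                                             times = nrow(obs)))]),
    stringsAsFactors = FALSE)
  stopifnot(nrow(df) == n)
  # %.17g keeps doubles bit-exact across the round trip
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tensor_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#1.")) {
    stop("not a GCT text file (missing #1.x magic)")
  }
  dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]])
  body <- read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                     check.names = FALSE, quote = "", comment.char = "")
  n_rmeta <- if (length(dims) >= 3L) dims[3L] else 0L
  genes <- as.character(body[[1L]])
  vals <- as.matrix(body[, -(seq_len(1L + n_rmeta)), drop = FALSE])
  storage.mode(vals) <- "double"
  cn <- colnames(vals)
  parts <- strsplit(cn, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("GCT column names must be '<drug>:<cell>'")
  }
  col_drug <- vapply(parts, `[`, "", 1L)
  col_cell <- vapply(parts, `[`, "", 2L)
  if (anyDuplicated(cn)) stop("duplicate (drug, cell) columns in GCT")
  drugs <- unique(col_drug); cells <- unique(col_cell)
  if (anyDuplicated(genes)) stop("duplicate gene rows in GCT")
  arr <- array(NA_real_, c(length(drugs), length(cells), length(genes)),
               dimnames = list(drugs, cells, genes))
  observed <- matrix(FALSE, length(drugs), length(cells),
                     dimnames = list(drugs, cells))
  for (k in seq_along(cn)) {
    v <- vals[, k]
    if (all(is.na(v))) next  # NA-filled column = unobserved pair
    if (anyNA(v)) {
      stop(sprintf(
        "ragged gene set for pair (%s, %s): all-or-nothing violated",
        col_drug[k], col_cell[k]))
    }
    arr[col_drug[k], col_cell[k], ] <- v
    observed[col_drug[k], col_cell[k]] <- TRUE
  }
  expression_tensor(arr, observed = observed)
}

write_tensor_gct <- function(tensor, path) {
  obs <- which(tensor$observed, arr.ind = TRUE)
  obs <- obs[order(obs[, 1L], obs[, 2L]), , drop = FALSE]
  labels <- paste(tensor$drugs[obs[, 1L]], tensor$cells[obs[, 2L]],
                  sep = ":")
  mat <- matrix(NA_real_, length(tensor$genes), nrow(obs),
                dimnames = list(NULL, labels))
  for (k in seq_len(nrow(obs))) {
    mat[, k] <- tensor$values[obs[k, 1L], obs[k, 2L], ]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.3",
               paste(length(tensor$genes), nrow(obs), 0L, 0L, sep = "\t")),
             con)
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  chr[is.na(mat)] <- "NA"
  df <- data.frame(id = tensor$genes, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a perturbagen-class (PCL) catalog
#'
#' Expects a tab-separated file with header `drug  class`, one row per
#' membership.  Classes with fewer than `min_size` members *present in a
#' given drug axis* are not usable for enrichment; the filter is applied by
#' [usable_classes()], not at read time.
#'
#' @param path TSV file path.
#' @param min_size minimum drugs per usable class (default 3).
#' @return A `pcl_catalog`: list with `classes` (named list of drug-id
#'   character vectors) and `min_size`.
#' @export
read_pcl_catalog <- function(path, min_size = 3L) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", quote = "",
                   comment.char = "")
  if (!all(c("drug", "class") %in% names(df))) {
    stop("PCL TSV must have columns drug, class")
  }
  pcl_catalog(split(df$drug, df$class), min_size = min_size)
}

#' @rdname read_pcl_catalog
#' @param classes named list mapping class name to character vector of
#'   drug identifiers.
#' @export
pcl_catalog <- function(classes, min_size = 3L) {
  stopifnot(is.list(classes), !is.null(names(classes)), min_size >= 1L)
  classes <- lapply(classes, function(x) unique(as.character(x)))
  structure(list(classes = classes, min_size = as.integer(min_size)),
            class = "pcl_catalog")
}

#' @rdname read_pcl_catalog
#' @param catalog a `pcl_catalog`.
#' @param drugs drug axis against which membership is counted.
#' @return `usable_classes()`: the subset of classes with at least
#'   `min_size` members among `drugs`, memberships restricted to `drugs`.
#' @export
usable_classes <- function(catalog, drugs) {
  kept <- lapply(catalog$classes, function(m) intersect(m, drugs))
  kept[lengths(kept) >= catalog$min_size]
}

#' @rdname read_pcl_catalog
#' @export
write_pcl_catalog <- function(catalog, path) {
  df <- data.frame(
    drug = unlist(catalog$classes, use.names = FALSE),
    class = rep(names(catalog$classes), lengths(catalog$classes)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cell-type annotations
#'
#' TSV with header `cell  category`; categories are typically
#' `cancer`, `immortalized`, `stem`, `primary`.
#'
#' @param path TSV file path.
#' @return A named character vector mapping cell identifier to category.
#' @export
read_cell_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", quote = "",
                   comment.char = "")
  if (!all(c("cell", "category") %in% names(df))) {
    stop("cell annotation TSV must have columns cell, category")
  }
  stats::setNames(df$category, df$cell)
}

#' @rdname read_cell_annotation
#' @param annotation named character vector (names = cells).
#' @export
write_cell_annotation <- function(annotation, path) {
  df <- data.frame(cell = names(annotation),
                   category = unname(annotation),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a query signature
#'
#' TSV with header `gene  direction`, direction in `up`/`down`.
#'
#' @param path TSV file path.
#' @return `read_signature()` returns a `query_signature`.
#' @export
read_signature <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", quote = "",
                   comment.char = "")
  if (!all(c("gene", "direction") %in% names(df))) {
    stop("signature TSV must have columns gene, direction")
  }
  if (!all(df$direction %in% c("up", "down"))) {
    stop("signature direction must be 'up' or 'down'")
  }
  query_signature(up = df$gene[df$direction == "up"],
                  down = df$gene[df$direction == "down"])
}

#' @rdname read_signature
#' @param signature a `query_signature`.
#' @export
write_signature <- function(signature, path) {
  df <- data.frame(
    gene = c(signature$up, signature$down),
    direction = rep(c("up", "down"),
                    c(length(signature$up), length(signature$down))),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
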