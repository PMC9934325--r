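#' Configuration for the synthetic LINCS-like generator
#'
#' The generator emulates the structure the imputation methods exploit:
#' drugs fall into latent perturbagen classes sharing a gene signature,
#' cells fall into types that modulate that signature multiplicatively and
#' shift it additively, and every (drug, cell, gene) value carries
#' idiosyncratic interaction plus measurement noise:
#' \deqn{z(d,c,g) = s(pcl(d), g) \cdot \rho(type(c)) + o(c,g) + i(d,c,g) + e(d,c,g)}
#' with `s ~ N(0, class_effect_sd)`, `rho(type) = 1 + N(0,
#' cell_modulation_sd)`, `o ~ N(0, cell_modulation_sd)`, `i ~ N(0,
#' interaction_sd)` and `e ~ N(0, noise_sd)`.  Setting
#' `cell_modulation_sd = 0` yields the "cell doesn't matter" regime in
#' which the tissue-agnostic baseline is unbeatable; large values yield the
#' regime where cell-aware methods win.
#'
#' @param n_drugs,n_cells,n_genes tensor dimensions (defaults 40 x 12 x
#'   100, a desk-scale echo of the 450-drug x 12-cell complete compendium).
#' @param n_pcls number of latent drug classes; `NULL` (default) draws
#'   class sizes log-uniformly in \[3, 20\] until the drug axis is
#'   partitioned, echoing the minimum-3-drugs rule of class enrichment.
#' @param n_cell_types number of cell types (default 4: cancer,
#'   immortalized, stem, primary), partitioning cells evenly.
#' @param class_effect_sd sd of the shared per-class gene signature
#'   (default 1, the z-score scale).
#' @param cell_modulation_sd sd of both the per-type multiplicative
#'   responsiveness and the per-cell additive offset (default 0.5).
#' @param interaction_sd sd of drug-by-cell idiosyncrasy (default 0.2).
#' @param noise_sd sd of measurement noise (default 0.3).
#' @param assay_fractions per-cell fraction of drugs observed, recycled
#'   over cells (default 1 = fully observed).  Values below ~0.05 emulate
#'   the starved cells of real compendia.
#' @param seed integer; generation is deterministic given the seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_drugs = 40L, n_cells = 12L, n_genes = 100L,
                             n_pcls = NULL, n_cell_types = 4L,
                             class_effect_sd = 1, cell_modulation_sd = 0.5,
                             interaction_sd = 0.2, noise_sd = 0.3,
                             assay_fractions = 1, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_cells >= 2L, n_genes >= 2L,
            n_cell_types >= 1L, class_effect_sd >= 0,
            cell_modulation_sd >= 0, interaction_sd >= 0, noise_sd >= 0,
            all(assay_fractions > 0), all(assay_fractions <= 1))
  if (!is.null(n_pcls)) stopifnot(n_pcls >= 1L, 3L * n_pcls <= n_drugs)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_pcls = if (is.null(n_pcls)) NULL else as.integer(n_pcls),
                 n_cell_types = as.integer(n_cell_types),
                 class_effect_sd = class_effect_sd,
                 cell_modulation_sd = cell_modulation_sd,
                 interaction_sd = interaction_sd, noise_sd = noise_sd,
                 assay_fractions = assay_fractions,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Partition n_drugs into classes of size log-uniform in [3, 20]
# (or into exactly n_pcls classes when requested).
draw_pcl_sizes <- function(n_drugs, n_pcls) {
  if (!is.null(n_pcls)) {
    base <- rep(n_drugs %/% n_pcls, n_pcls)
    extra <- n_drugs %% n_pcls
    if (extra > 0L) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    return(base)
  }
  sizes <- integer(0)
  remaining <- n_drugs
  while (remaining > 0L) {
    s <- round(exp(runif(1, log(3), log(20))))
    s <- min(s, remaining)
    if (remaining - s > 0L && remaining - s < 3L) s <- remaining  # no runt
    sizes <- c(sizes, s)
    remaining <- remaining - s
  }
  sizes
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param config a [generator_config()].
#' @return List with `tensor` (an `expression_tensor`), `pcl_catalog`,
#'   `cell_annotation` (named category vector) and `truth` (the latent
#'   components: `class_signature` matrix, `responsiveness` per type,
#'   `cell_offset` matrix, `pcl_of_drug`, `type_of_cell`, and the config),
#'   for oracle tests.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    nd <- config$n_drugs; nc <- config$n_cells; ng <- config$n_genes
    drugs <- sprintf("drug%03d", seq_len(nd))
    cells <- sprintf("cell%02d", seq_len(nc))
    genes <- sprintf("g%04d", seq_len(ng))
    categories <- c("cancer", "immortalized", "stem", "primary")
    types <- categories[((seq_len(config$n_cell_types) - 1L) %% 4L) + 1L]
    if (config$n_cell_types > 4L) {
      types <- sprintf("%s%d", types,
                       (seq_len(config$n_cell_types) - 1L) %/% 4L + 1L)
    }
    type_of_cell <- types[((seq_len(nc) - 1L) %% config$n_cell_types) + 1L]
    names(type_of_cell) <- cells

    sizes <- draw_pcl_sizes(nd, config$n_pcls)
    pcl_names <- sprintf("PCL%02d", seq_along(sizes))
    pcl_of_drug <- rep(pcl_names, sizes)[seq_len(nd)]
    names(pcl_of_drug) <- drugs

    class_signature <- matrix(rnorm(length(sizes) * ng, 0,
                                    config$class_effect_sd),
                              length(sizes), ng,
                              dimnames = list(pcl_names, genes))
    responsiveness <- 1 + rnorm(length(types), 0, config$cell_modulation_sd)
    names(responsiveness) <- types
    cell_offset <- matrix(rnorm(nc * ng, 0, config$cell_modulation_sd),
                          nc, ng, dimnames = list(cells, genes))

    vals <- array(0, c(nd, nc, ng), dimnames = list(drugs, cells, genes))
    for (j in seq_len(nc)) {
      base <- class_signature[pcl_of_drug, , drop = FALSE] *
        responsiveness[type_of_cell[j]]
      vals[, j, ] <- base +
        matrix(cell_offset[j, ], nd, ng, byrow = TRUE) +
        matrix(rnorm(nd * ng, 0, config$interaction_sd), nd, ng) +
        matrix(rnorm(nd * ng, 0, config$noise_sd), nd, ng)
    }

    fractions <- rep_len(config$assay_fractions, nc)
    observed <- matrix(TRUE, nd, nc, dimnames = list(drugs, cells))
    if (any(fractions < 1)) {
      for (j in seq_len(nc)) {
        keep_n <- max(2L, round(fractions[j] * nd))
        if (keep_n < nd) {
          observed[sample.int(nd, nd - keep_n), j] <- FALSE
        }
      }
      # evaluability: every drug must stay observed in >= 2 cells.  Repair
      # deficient drugs by re-observing them in random extra cells.
      deficient <- which(rowSums(observed) < 2L)
      for (i in deficient) {
        candidates <- which(!observed[i, ])
        add <- sample(candidates, 2L - sum(observed[i, ]))
        observed[i, add] <- TRUE
      }
      if (any(colSums(observed) < 2L)) {
        stop("config cannot satisfy evaluability: a cell has < 2 observed drugs")
      }
      for (j in seq_len(nc)) {
        vals[!observed[, j], j, ] <- NA_real_
      }
    }

    tensor <- expression_tensor(vals, observed = observed)
    catalog <- pcl_catalog(split(drugs, pcl_of_drug), min_size = 3L)
    list(tensor = tensor, pcl_catalog = catalog,
         cell_annotation = stats::setNames(
           sub("[0-9]+$", "", type_of_cell), cells),
         truth = list(class_signature = class_signature,
                      responsiveness = responsiveness,
                      cell_offset = cell_offset,
                      pcl_of_drug = pcl_of_drug,
                      type_of_cell = type_of_cell,
                      config = config))
  })
}

#' Write a named synthetic fixture to disk
#'
#' Three presets echo, at desk scale, the shapes of real compendia:
#' \describe{
#'   \item{`tiny`}{6 drugs x 4 cells x 20 genes, fully observed.}
#'   \item{`complete_like`}{40 drugs x 12 cells x 100 genes, fully
#'     observed (the complete 450 x 12 compendium, scaled down).}
#'   \item{`sparse_like`}{120 drugs x 20 cells x 100 genes with about 75%
#'     of (drug, cell) pairs missing, the sparseness of the 1330 x 80
#'     compendium.}
#' }
#' Each fixture is written in both tensor formats plus PCL and cell
#' annotation TSVs; files are byte-identical for a fixed seed.
#'
#' @param name preset name.
#' @param dir output directory (created if needed).
#' @param seed integer (default 7).
#' @return Named character vector of the written file paths (elements
#'   `long`, `gct`, `pcl`, `cells`), with the generated dataset attached as
#'   attribute `dataset`.
#' @export
make_fixture <- function(name = c("tiny", "complete_like", "sparse_like"),
                         dir = ".", seed = 7L) {
  name <- match.arg(name)
  config <- switch(name,
    tiny = generator_config(n_drugs = 6L, n_cells = 4L, n_genes = 20L,
                            n_pcls = 2L, n_cell_types = 2L, seed = seed),
    complete_like = generator_config(n_drugs = 40L, n_cells = 12L,
                                     n_genes = 100L, seed = seed),
    sparse_like = generator_config(
      n_drugs = 120L, n_cells = 20L, n_genes = 100L,
      assay_fractions = c(0.88, 0.66, 0.50, 0.42, 0.36, 0.30, 0.27, 0.24,
                          0.22, 0.20, 0.18, 0.16, 0.14, 0.12, 0.10, 0.08,
                          0.06, 0.05, 0.04, 0.04),
      seed = seed))
  ds <- generate_dataset(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    long = file.path(dir, sprintf("%s.tsv", name)),
    gct = file.path(dir, sprintf("%s.gct", name)),
    pcl = file.path(dir, sprintf("%s_pcls.tsv", name)),
    cells = file.path(dir, sprintf("%s_cells.tsv", name)))
  write_tensor(ds$tensor, paths[["long"]], format = "long")
  write_tensor(ds$tensor, paths[["gct"]], format = "gct")
  write_pcl_catalog(ds$pcl_catalog, paths[["pcl"]])
  write_cell_annotation(ds$cell_annotation, paths[["cells"]])
  attr(paths, "dataset") <- ds
  paths
}
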