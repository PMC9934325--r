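Package: conncf
Title: Cell-Specific Connectivity Mapping with Imputation of Missing
    Drug-Cell Expression Profiles
Version: 0.1.0
Authors@R:
    person("conncf", "developers", email = "conncf@example.org",
           role = c("aut", "cre"))
Description: Tools for connectivity mapping when the drug-by-cell matrix of
    differential gene-expression profiles is incomplete.  Missing (drug, cell)
    expression profiles are imputed by four methods: a tissue-agnostic
    cross-cell median, a median-of-medians combining drug and cell marginals,
    neighborhood collaborative filtering with adjusted-cosine drug similarity,
    and regularized low-rank matrix factorization fitted by stochastic
    gradient descent over observed entries (Funk SVD).  Connectivity of query
    signatures against true or imputed profiles is scored with the weighted
    Kolmogorov-Smirnov enrichment statistic, the weighted connectivity score
    (WCS) and its mean-scaled normalization (NCS).  Imputation quality is
    evaluated by constrained five-fold cross-validation, a head-weighted
    Spearman rank correlation, a per-cell downsampling experiment, and
    permutation-based drug-set (perturbagen class) enrichment.  A synthetic
    data generator produces LINCS-like z-score tensors with known latent drug
    classes, cell-type-specific modulation and realistic missingness, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
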