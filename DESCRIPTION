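Package: bcnorm
Title: Blind Compressive Normalization of High-Throughput Data Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes unknown low-rank confounding bias from feature-by-sample
    high-throughput data matrices (transcriptomics, proteomics, metabolomics)
    without quantitative standards, replicates of known batches, or annotated
    confounders. Correlated feature and sample pairs detectable in the data are
    turned into sparse linear measurements of the bias matrix, which is then
    recovered by least squares on the fixed-rank matrix manifold (Riemannian
    conjugate gradient with truncated-SVD retraction) and subtracted. Includes
    a matrix-normal simulator with block-structured redundancies, low-rank bias
    and MAR/MNAR missingness, entry/k-sparse/blind sensing operators, rank
    selection by measurement hold-out, and a differential-expression benchmark
    against quantile normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    limma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
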