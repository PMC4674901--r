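Package: fractionator
Title: Fractionation Dynamics and Model Discrimination After Whole Genome
    Doubling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the loss of duplicate genes (fractionation) after a
    whole genome doubling under a geometric deletion-length model with
    overlap "skipping", computes the deletion-overlap probabilities in
    closed form and by independent oracle summation or quadrature, and
    discriminates the gene-by-gene deletion regime (mean deletion length
    mu = 1) from the segmental regime (mu > 1) by minimal
    Kolmogorov-Smirnov distance between observed run-length cumulatives
    and simulated reference cumulatives on a (mu, N, deleted-proportion)
    grid.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
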