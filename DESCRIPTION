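Package: fdscan
Title: Window-Based ABBA-BABA Statistics and Introgression Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Patterson's D and the admixture-proportion estimators
    f_G, f_hom and the dynamic estimator f_d in genomic windows, together
    with nucleotide diversity (pi) and absolute divergence (d_XY) with
    pairwise missing-data handling. Includes a coalescent simulator of
    four-taxon sequence windows with recombination, instantaneous admixture
    or ancestral-structure histories and finite-site HKY mutation, and an
    evaluation framework that measures how well each statistic quantifies
    the introgression proportion and whether outlier windows show reduced
    between-taxon divergence under gene flow, ancestral structure and null
    histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    Biostrings,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
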