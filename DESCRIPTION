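Package: oligostab
Title: Single-Nucleotide Oligotyping and Temporal Stability Analysis of
    Amplicon Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Entropy-based decomposition of aligned 16S rRNA amplicon reads
    into single-nucleotide oligotypes, best-hit taxonomy assignment against a
    lineage-annotated reference, multi-level community abundance tables
    (phylum to oligotype, including de novo 97% OTU binning), Bray-Curtis
    non-metric multidimensional scaling with per-group covariance ellipses,
    and the within-host versus between-host stability statistics (mean,
    standard deviation, coefficient of variation, anomaly series, oligotype
    fingerprints) used to show that dental-plaque communities are
    individualized at single-nucleotide resolution.  Includes a
    Dirichlet-multinomial synthetic community generator emulating an
    eight-individual, eight-timepoint plaque sampling design so the whole
    pipeline can be exercised and validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
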