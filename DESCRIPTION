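Package: hgadmix
Title: Haplogroup Frequency Bases, Central-Vector Clustering and Admixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing populations by their mitochondrial haplogroup
    frequency distributions. Builds a common haplogroup basis from per-individual
    haplogroup calls (hierarchical label tokenization, cumulating or cutting
    assignment, database-wide prevalence filtering, Spearman rank-correlation
    selection of jointly propagating haplogroups), finds local condensation
    centres of the population frequency vectors with a growing central-vector
    clustering algorithm, models any population as an optimal weighted linear
    combination of the central vectors by gradient search (an admixture model
    with normalized error reporting), and validates haplogroup-based Euclidean
    distance matrices against reference (e.g. Fst) matrices by matrix
    correlation and Mantel permutation tests. Includes a synthetic-data
    generator with planted ancestral profiles for end-to-end testing, and a
    pipeline driver with plain-text input/output formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
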