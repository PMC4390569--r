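Package: ethoscan
Title: Heritable Variation in Courtship Behavior from Scan-Sampled Ethograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies heritable variation in Drosophila male courtship
    patterns from scan-sampled ordinal behavior records. Builds male mating
    progression (MMP) scores and per-individual first-order Markov transition
    matrices over condensed behavior categories, partitions trait variance
    into block and line components to estimate broad-sense heritability by
    the method of moments, classifies lines by their proportion of
    noninitiating males with an exponential versus two-component Normal
    mixture comparison (AIC), summarises transition structure by principal
    component factoring with varimax rotation, and scans line means against
    inbred-line genotypes with Bonferroni control and QQ diagnostics. A
    synthetic-study generator with known ground truth emulates the full
    study design so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    MASS,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
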