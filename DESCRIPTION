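Package: sicompat
Title: Mapping Multi-Locus Gametophytic Self-Incompatibility from Diallel
    Pollination Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting multi-locus gametophytic self-incompatibility
    (SI) in outbreeding grasses from diallel cross-pollination data. Implements
    the SI50 population index (a four-parameter logistic fitted to the quantile
    curve of ordinal compatibility scores), Compatibility Components (principal
    components of the genotype-by-genotype pollination-distance structure,
    matched across replicate years), and a single-marker genome-wide association
    scan of component scores with minor-allele-frequency filtering, population
    structure covariates and Bonferroni thresholds. Includes a forward simulator
    of a two-locus (S, Z) complementary gametophytic SI population with linked
    SNP markers for power and recovery studies.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
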