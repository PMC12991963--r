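Package: exclodiv
Title: Diversity Trends and Biotic Homogenization in Paired Exclosure Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for long-term paired herbivore-exclosure
    experiments on seedling and sapling communities. Computes plot-level
    alpha diversity (richness, Shannon, inverse Simpson) on
    Hellinger-transformed abundances, abundance-based multiple-site
    Bray-Curtis beta diversity partitioned into balanced-variation and
    abundance-gradient components, plot-level leave-one-out jackknife
    uncertainty, treatment-by-time linear mixed models and linear models,
    and pairwise cross-site z-test contrasts of interaction effect sizes.
    Includes a seeded generator of synthetic exclosure surveys so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
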