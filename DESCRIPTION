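Package: nurtureR
Title: Genetic Nurture Analysis with Transmitted and Non-Transmitted Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based analysis of genetic nurture versus direct genetic
    transmission. Infers which parental haplotype segments were transmitted to
    an offspring from phased genotypes of parent-offspring pairs and trios
    using tile matching with breakpoint refinement, builds polygenic scores on
    transmitted and non-transmitted haplotypes, and estimates nurture and
    transmission effects with family-clustered mixed models, full-information
    maximum-likelihood path models (parent-of-origin contrasts, Wald equality
    tests) and bootstrap mediation decompositions. Includes a synthetic family
    simulator (Haldane meiosis on a genetic map, assortative mating, liability
    threshold phenotypes with a nurture path mediated by parental phenotype)
    so the full pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
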