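Package: gcamap
Title: Combining-Ability Genetics and QTL Mapping for NCII Testcross Designs
Version: 0.1.0
Authors@R:
    person("gcamap", "developers", email = "gcamap@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic basis of general combining
    ability (GCA) in biparental recombinant inbred line (RIL) populations
    crossed to testers under the North Carolina Design II. Includes a
    simulator for RIL genomes and multi-environment testcross phenotypes,
    best linear unbiased estimates (BLUEs) and ANOVA variance components
    with Knapp broad-sense heritability, GCA/SCA estimation and the
    sigma2GCA/sigma2SCA ratio, Haley-Knott interval mapping and composite
    interval mapping with permutation thresholds, 1.5-LOD support intervals,
    and rules for co-localizing and classifying QTL detected for line per se
    performance versus GCA effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
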