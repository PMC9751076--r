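Package: divstab
Title: Biodiversity Effects and Temporal Stability in Grassland Diversity Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of long-term grassland
    biodiversity experiments. Implements the additive partitioning of net
    biodiversity effects into complementarity and selection effects (annually
    and over multi-year windows with monoculture-failure exclusion and
    quartile-fence outlier screening), temporal stability and species
    synchrony indices over rolling windows, power-law decompositions of
    richness-stability slopes, and standardized recursive path analysis with
    bootstrap inference linking richness, biodiversity effects, asynchrony,
    and population stability to community stability. Ships a synthetic
    community-dynamics generator with known ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
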