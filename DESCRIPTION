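Package: gutsampler
Title: Sampling-Design Diagnostics for Poultry Gut Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating 16S rRNA amplicon sampling designs in broiler
    flocks from ASV count tables: bird-accumulation curves for intra-flock
    sample-size sufficiency, cecal pouch pair similarity statistics, cloacal
    swab proxy assessment along the alimentary tract (distance-to-swab
    profiles, family-level correlations, per-bird distance-decay), a
    permutation-based cecal enrichment contrast, negative-control contaminant
    scoring combining frequency and prevalence evidence, cumulative sum
    scaling normalization, and community distance/ordination utilities
    (Bray-Curtis, weighted UniFrac, PCoA, ANOSIM). Includes a synthetic flock
    generator with known ground truth so every stage is testable without
    deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
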