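Package: codamarker
Title: Cross-Study Compositional Biomarker Discovery for Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Maintainer", "codamarker", email = "codamarker@example.org",
           role = c("aut", "cre"))
Description: Identifies stool-metagenome biomarkers of melanoma immunotherapy
    response that are consistent across published cohorts. Implements
    multinomial-regression differential ranking of compositional taxonomic and
    functional profiles, top-k association calling, a two-rule cross-study
    consolidation scheme with a validation pass, log-ratio group assessment,
    PERMANOVA on Aitchison and Bray-Curtis distances, profile-level detection
    of donor-derived species after fecal microbiota transplantation, and
    ranking of species by linked functional biomarkers. A synthetic multi-study
    generator with planted effects, study-specific bias and FMT engraftment
    structure makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
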