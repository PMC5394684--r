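Package: adsubtype
Title: Atrophy-Pattern Subtyping of Alzheimer's Disease from MRI Visual Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies Alzheimer's disease patients into four atrophy-pattern
    subtypes (typical, limbic-predominant, hippocampal-sparing, no atrophy)
    from three MRI visual rating scales (MTA, PA, GCA-F) using age-adjusted
    abnormality cutoffs, and provides the characterization toolkit around the
    classifier: AVLT memory-component derivation and impairment flagging,
    backward multiple regression with all-subsets general dominance analysis
    and bootstrap stability screening, longitudinal linear mixed-effects slope
    models with pairwise contrasts, random-forest group discriminability, and
    weighted-kappa rater reliability. A seeded synthetic cohort generator
    emulates the structure of an ADNI-like sample so every stage is testable
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
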