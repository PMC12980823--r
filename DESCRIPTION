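Package: pfascope
Title: Swim Respirometry Bioenergetics and PFAS Tissue Distribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for whole-organism bioenergetics and perfluoroalkyl
    substance (PFAS) toxicokinetics in small-bodied fish. Converts raw
    intermittent-flow swim-respirometry oxygen traces into background-corrected,
    allometrically mass-standardized oxygen consumption rates; derives standard
    and maximum metabolic rate, aerobic scope and critical swimming speed
    (Ucrit) from incremental-velocity trials via an exponential rate-speed
    model; computes tissue-residue distribution metrics for PFOS and PFOA
    (compound sums, PFOS fraction, tissue percent shares, organ-to-blood
    ratios, fold-change ranges) with left-censoring at method reporting
    limits; summarizes somatic indices, egg production and mortality; and
    fits concentration-by-temperature interaction models with per-temperature
    simple slopes. Includes seeded generators for synthetic oxygen traces,
    tissue-residue cohorts and egg-count series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
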