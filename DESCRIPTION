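Package: preysel
Title: Prey-Selection Meta-Analysis for Predator Diet Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-analysis of predator prey selection from diet and
    prey-availability data. Computes Jacobs' selectivity index from relative
    frequency of occurrence, pools study-level values into per-species
    preference tests, and supports an iterative preference averaging (IPA)
    estimator that accounts for species missing from individual studies.
    Includes a scat-production allometry for biomass-corrected selection,
    all-subsets Gaussian linear modelling with information-criterion weights
    and model averaging for drivers of selection, segmented (breakpoint)
    regression of selection against log prey mass to delimit accessible and
    preferred prey weight ranges, and a synthetic multi-study data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
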