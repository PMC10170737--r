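Package: htnrec
Title: Neighborhood-Based Drug Recommender for First-Line Antihypertensive Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid clinical decision support engine for first-line
    antihypertensive drug choice. Combines neighborhood-based collaborative
    filtering over routine-care patient records (simple-matching-coefficient
    patient similarity, binary patient-therapy matrices, blood-pressure
    endpoint outcome prediction) with an evidence-based contraindication rule
    engine for labeling and post-filtering of treatment options. Includes a
    case-vignette expert-panel evaluation framework (top-N agreement,
    majority-vote and inter-rater statistics) and a seeded synthetic
    electronic-health-record generator with planted, recoverable
    subgroup-treatment effects for benchmarking. Ships only a synthetic,
    non-clinical demonstration rule base; not for clinical use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
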