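Package: gcredist
Title: Probabilistic Redistribution of Ill-Defined Causes of Death and
    Fatal Burden Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for national burden-of-disease studies built on
    cause-of-death microdata. Maps ICD-10 underlying causes of death to a
    GBD-style four-level cause hierarchy, redistributes ill-defined deaths
    ("garbage codes") onto specific causes with a four-step probabilistic
    algorithm that exploits multiple-causes-of-death (MCOD) information --
    predefined ICD target codes, MCOD-defined packages, internal
    redistribution within the certificate, and all-cause redistribution --
    and quantifies the fatal burden as deaths and Standard Expected Years
    of Life Lost (SEYLL), reported as counts, crude rates and
    age-standardized rates with Monte-Carlo uncertainty intervals.
    Includes a synthetic microdata generator with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
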