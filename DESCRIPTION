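Package: cdtk
Title: Cadmium Toxicokinetics, Reverse Dosimetry and Urinary Biomonitoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lifetime multi-compartment toxicokinetic simulation of cadmium
    disposition and its inversion ("reverse dosimetry"): converts group
    geometric-mean urinary cadmium (micrograms per gram creatinine) into the
    dietary intake (micrograms per day) and cigarette smoking rate (packs per
    day) that reproduce it.  Includes lognormal biomonitoring statistics
    (geometric means, detection-limit substitution, threshold exceedance,
    group comparisons with Dunnett post-hoc tests), a synthetic cohort
    generator emulating the Thai Bangkok and Mae Sot survey structure, and
    comparisons against WHO and EFSA tolerable-intake and urinary-threshold
    reference values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    multcomp,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
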