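Package: tonocorr
Title: Tonometry Correction Formulas and Method-Comparison Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing intraocular pressure (IOP) readings from
    Goldmann applanation tonometry (GAT) and dynamic contour tonometry
    (DCT). Implements a registry of ten published GAT correction formulas
    (Shimmyo, ShimmyoR, Elsheikh 2009/2011, Srodka, Chihara, Doughty,
    Foster, Kohlhaas, Ehlers), paired method-comparison statistics
    (signed and absolute differences with paired t-tests), Bland-Altman
    agreement analysis with fixed- and proportional-bias detection,
    Monte-Carlo Lilliefors normality testing, paired t-test sample-size
    computation via the noncentral t distribution, and a moment-calibrated
    synthetic cohort generator so the full pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
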