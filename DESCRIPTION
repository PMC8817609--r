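Package: ctiFR
Title: CT-Derived Instantaneous Wave-Free Ratio from Coronary Centerline Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, reproducible pipeline for a coronary computed
    tomography angiography (CCTA) derived instantaneous wave-free ratio
    (iFR). Models a coronary artery as a centerline tree with lumen radii,
    assigns boundary conditions from left-ventricular myocardial mass
    (allometric mass-flow relation) and Murray's law, solves a steady
    diastolic reduced-order pressure field (Poiseuille viscous integral
    plus post-stenotic expansion loss) and reads the wave-free Pd/Pa index
    at a sensor point distal to the lesion (ischemia cutoff 0.89).
    Includes a seeded synthetic vessel/cohort generator emulating stenosed
    epicardial trees with noisy invasive measurements, and the full
    diagnostic-evaluation battery: confusion metrics with exact binomial
    confidence intervals, empirical ROC/AUC with DeLong comparison,
    Bland-Altman agreement, Fisher r-to-z correlation comparison, and
    decision-curve analysis.
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
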