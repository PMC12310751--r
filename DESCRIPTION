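Package: tdpcohort
Title: Simulation and Analysis of Torsade de Pointes Inducibility in
    Chronic AV Block Dog Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying dofetilide-induced Torsade de Pointes (TdP)
    inducibility in the chronic complete atrioventricular block (CAVB) dog
    model. Provides a statistical generator for synthetic CAVB cohorts
    (phenotype-specific truncated-normal traits, paired baseline-to-dofetilide
    shifts, Poisson arrhythmic-event streams), repolarization metrics
    (JT derivation, Van de Water / Fridericia / Bazett rate correction,
    short-term variability of beat-to-beat repolarization), the standard
    arrhythmic-event point scoring with top-three-event arrhythmia score and
    the >= 3 TdP episode inducibility classifier, and the group-comparison
    statistics (mean +/- SD summaries, unpaired t-tests, two-way ANOVA with
    Bonferroni-adjusted planned contrasts) used to build Table-1-style
    reports for such cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
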