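Package: metstab
Title: Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing genotype-by-environment interaction in
    multi-environment trials (METs). Implements the AMMI model (combined
    ANOVA plus singular value decomposition of the doubly-centred
    interaction matrix) with Gollob tests, biplot coordinates, the nominal
    (adaptation) plot and the AMMI stability value; GGE biplot geometry
    (which-won-where polygon, mean-versus-stability ranking along the
    average environment coordinate, ideal-genotype and ideal-environment
    comparisons); a suite of parametric, nonparametric and BLUP-based
    stability statistics (Wricke's ecovalence, joint regression, Huehn and
    Thennarasu rank statistics, Lin-Binns superiority, geometric
    adaptability index, RPGV/HMRPGV); and the multi-trait genotype-ideotype
    distance index (MGIDI) with factor analysis, selection gains and a
    strengths-weaknesses decomposition. Includes a split-plot MET simulator
    with planted low-rank interaction for validation, and embedded rice
    grain-yield fixtures from a published two-regime irrigation trial.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
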