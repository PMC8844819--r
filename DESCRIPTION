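Package: growthpheno
Title: Developmental Brain-Region Growth Trajectories and Behavioral
    Phenotype Analysis for Two-Genotype Mouse Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit linking developmental brain-region volumetrics
    to behavioral phenotypes in two-genotype (wild-type vs. mutant), two-age
    (P7/P60) mouse studies. Computes per-subject region growth indices,
    wild-type growth trajectories, percent deviations of mutant adult
    volumes from trajectory-predicted volumes with one-sample tests, and
    within-genotype growth-correlation divergence maps. Implements acoustic
    startle psychophysics: per-intensity trial summarization, sigmoid
    (logistic) fits to log-normalized startle curves with derived 5 percent
    thresholds, midpoints, slopes and saturation, traditional paired-baseline
    group thresholds, low/high dB-module mixed ANOVAs, and prepulse
    inhibition and habituation scoring. Also provides formula-defined
    behavioral indices (novel-object discrimination, social preference,
    puzzle-box percent-of-maximum-time), a region-status to behavior
    concordance map, and synthetic-data generators with known ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
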