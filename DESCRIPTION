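Package: stresspheno
Title: Multi-Level Behavioral Phenotyping of Stress Susceptibility in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping stress-exposed rodents from multi-test
    behavioral batteries. Implements percentile-threshold 0-3 severity scoring
    of behavioral variables, an eight-variable composite severity score, and a
    two-step classification of foot-shocked animals into resilient,
    susceptible-freezer and susceptible-escaper phenotypes. Companion modules
    compute sleep-architecture metrics and scores from 5-s-epoch hypnograms
    (with a rule-based vigilance-state classifier), count c-Fos-positive
    nuclei in two-channel fluorescence images and derive regional activation
    scores, and wrap the nonparametric statistics (Kruskal-Wallis with Dunn
    post hoc, Friedman, signed-rank, Spearman) used to compare phenotypes.
    A synthetic cohort generator produces behavioral tables, hypnograms,
    epoch-feature series and images with the statistical structure the
    analysis assumes, so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
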