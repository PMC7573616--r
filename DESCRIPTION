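Package: lickometry
Title: Lick Microstructure, Brief-Access Gustometry, and Chorda Tympani
    Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rodent taste-driven licking behaviour and
    peripheral taste-nerve recordings. Segments 23-h lick streams into meals
    and bursts and computes whole-meal and intra-meal microstructure
    variables; converts brief-access gustometer trials into standardized
    lick ratios using water-training interlick intervals; rectifies and
    leaky-integrates whole-nerve chorda tympani traces, measures
    baseline-subtracted response heights, and normalizes them to bracketing
    reference (ammonium chloride) applications with a stability QC; and
    provides the accompanying statistical battery (two-tailed t tests,
    split-plot mixed ANOVA, Bonferroni-adjusted pairwise comparisons). A
    hierarchical synthetic-data generator emulates gustometer and
    lickometer event streams and raw nerve traces with known ground truth
    so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
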