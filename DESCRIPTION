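Package: trainadapt
Title: Geometric Modelling of Training Adaptation from Athlete Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling athletic training adaptation from
    longitudinal monitoring data. Computes session-RPE internal load,
    training monotony, training strain and the acute:chronic workload
    ratio from training logs; converts competition results into the
    percentage-of-personal-best-time (%PBT) performance index; and fits a
    geometric classifier that partitions the unit square of two weekly
    training indicators into adaptation and maladaptation regions via
    agglomerative clustering under several dissimilarities, convex-hull
    pattern construction and a nearest-region decision map. The ratio of
    the two region areas, the Geometric Activity Performance Index (GAPI),
    summarises a season in a single number. Jittering with Gaussian noise
    and ensemble averaging stabilise the fit on small samples; Spearman
    rank and Blomqvist beta statistics with Bonferroni-Holm correction
    relate GAPI to performance outcomes. A synthetic-cohort generator with
    known ground-truth decision rules supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    jsonlite,
    pracma,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
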