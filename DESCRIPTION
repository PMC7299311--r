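Package: trajpc
Title: Trajectory Profile Clustering for Longitudinal Disease Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based identification and early prediction of chronic-disease
    subtypes from multi-year, multi-variable patient trajectories. Patients are
    discretized against training-population baseline medians into binary trajectory
    profiles, linked by profile agreement into a weighted patient-patient network,
    and clustered into subtypes by Louvain modularity maximization. Held-out
    patients are assigned to subtypes from baseline data alone and re-assigned at
    later timepoints to score prediction accuracy. Includes subtype-contrast
    statistics (Mann-Whitney U, Fisher exact, Bonferroni budget), a synthetic
    longitudinal cohort generator with planted subtypes, JSON model artifacts, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
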