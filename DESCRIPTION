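Package: alsconsensus
Title: Consensus Stratification and Challenge Scoring for Longitudinal ALS Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for crowdsourced patient-stratification challenges on
    longitudinal clinical records, built around amyotrophic lateral
    sclerosis (ALS) cohorts in a long-format tabular dialect.  Derives
    ground-truth outcomes (ALSFRS progression slope, censored survival),
    scores prediction sets with permutation-null z-scores and a
    censoring-aware concordance index, integrates many independent patient
    clusterings into consensus clusters through a size-weighted
    co-clustering matrix with permutation false-discovery-rate control,
    screens clinical features that discriminate the clusters via an
    integrated ANOVA/Fisher permutation-rank procedure, and assigns new
    patients to clusters by uncentered correlation against z-normalized
    cluster profiles.  A synthetic cohort generator with planted cluster
    structure makes every stage testable without access-restricted
    registry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    survival,
    cluster,
    optparse
Config/testthat/edition: 3
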