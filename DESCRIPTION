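Package: asthmanet
Title: Comorbidity Networks and Seasonality of Asthma Hospitalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing adult asthma hospital admissions: canonicalization
    of ICD-10 discharge codes (with merging of all J45 asthma subcodes), cohort
    inclusion filtering and baseline demographic summaries, yearly trend and
    gender-proportion statistics, classical additive seasonal decomposition of
    monthly admission series per sex, and age-group comorbidity co-occurrence
    networks built from per-admission diagnosis cliques. Networks are scored with
    normalized betweenness centrality and Louvain communities, and clinician-defined
    diagnosis categories are ranked by their relative influence anchored on the
    asthma code. A fully configurable synthetic admission-record generator
    reproduces the statistical structure the analysis assumes (demographics,
    yearly and monthly admission patterns, planted comorbidity blocks), so the
    whole pipeline is testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
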