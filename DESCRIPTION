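Package: progmod
Title: Differential Equation and Event-Based Models of Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing long-term biomarker trajectories and
    orderings of biomarker abnormality from short-term longitudinal cohort
    data. Implements the differential equation model (per-subject rates of
    change, Gaussian-process rate regression, trajectory reconstruction by
    integration, t0 anchoring and continuous patient staging), the
    event-based model in both Gaussian-mixture and kernel-density-mixture
    formulations (maximum-likelihood event sequences, MCMC posteriors over
    orderings, positional variance diagrams and discrete staging),
    preprocessing of longitudinal biomarker tables (covariate adjustment,
    region-of-interest aggregation, z-scoring to controls, floor-score
    handling for cognitive tests), rank-based comparison of orderings
    within and between patient groups, and a synthetic-cohort generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
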