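Package: megclust
Title: Spatio-Spectral Cluster-Permutation Inference for MEG Power Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links source-space magnetoencephalography (MEG) power change to
    cognitive change in pre/post two-arm trials. Implements node-by-frequency
    age-partialed Spearman correlation maps between post/pre power ratios and a
    behavioural post/pre ratio, sign-consistent spatio-spectral clustering with
    persistence and extent filters, cluster-mass statistics with max-statistic
    permutation control of the familywise error rate, ROI occupancy tables, and
    the accompanying trial-level analytics (baseline comparisons, random-intercept
    pre/post mixed models, Hedges g, respondent analysis, simulation-based power
    and positive predictive value). A synthetic-data generator produces complete
    cohort plus power-tensor datasets with a planted spatio-spectral effect so the
    whole pipeline can be exercised and calibrated without access to raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    Matrix,
    utils,
    graphics,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
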