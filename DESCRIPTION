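Package: criticalTC
Title: Temporal Correlations and Critical Network Dynamics in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying proximity to critical network dynamics from
    intracranial EEG-like recordings. Implements a tunable branching-style
    neuronal network simulator with sleep-like off-periods, interictal-spike
    events and medication-like excitability scaling; the temporal-correlation
    (TC) statistic computed from the autocorrelation of log high-gamma band
    power; slow-wave state annotation via a vigilance index, interictal-spike
    rate binning and medication day classification; nonparametric group
    inference (Brunner-Munzel tests with relative effects, paired Wilcoxon,
    Benjamini-Hochberg correction, Kolmogorov-Smirnov uniformity checks); and
    a seeded synthetic-data generator producing multichannel recordings and
    cohort metadata with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
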