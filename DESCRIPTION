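Package: plvmotif
Title: Longitudinal Phase-Locking Connectivity Ratios and Network Motif
    Permutation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal source-space MEG functional
    connectivity of the default mode network. Simulates two-group, two-session
    cohorts of band-limited, von Mises phase-coupled node time series with
    analytically known phase-locking value (PLV); computes per-trial PLV
    connectivity matrices and post/pre connectivity ratios; tests link-wise
    group differences with a sex-adjusted Freedman-Lane permutation ANCOVA;
    extracts connected significant sub-networks (motifs) under node-coverage
    and link-density criteria with max-mass permutation correction; summarises
    motifs by per-subject degree, Cohen's d, one-sample t-tests against unity
    and leave-one-out logistic-regression classification; and runs the
    parallel repeated-measures ANCOVA on per-tract diffusion (DTI) metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
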