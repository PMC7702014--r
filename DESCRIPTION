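Package: szjitter
Title: Jitter Analysis of Spontaneous Seizures in Local Field Potential Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the variability of spontaneous epileptiform
    activity in extracellular local field potential (LFP) recordings from
    in-vitro preparations such as organotypic hippocampal cultures. Provides
    zero-phase Butterworth preprocessing, dual-threshold population-spike and
    seizure detection, an inter-spike-interval jitter statistic with optimal
    seizure alignment, sliding-window jitter traces with spontaneous
    state-transition calling, Fano-factor variability summaries, asymmetric
    least squares baseline estimation with delta-F/F analysis of calcium
    fluorescence traces, and a seeded synthetic-signal generator that produces
    ground-truth epileptiform recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
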