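Package: tachometry
Title: Tachometric-Curve and Selection-History Analysis for Urgent
    Saccadic Choice Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing trial-level behavioral data from urgent
    (compelled) visual search tasks, in which the go signal precedes the
    color cue so that choices span a continuum from uninformed guesses to
    fully informed saccades. Implements tachometric-curve estimation
    (sliding-bin accuracy as a function of processing time) with
    Agresti-Coull binomial confidence intervals, floor/ceiling accuracy
    summaries and bootstrap comparisons; post-hoc classification of trials
    by target-color, target-location and outcome histories, including
    joint outcome-gated and lagged single-event variants; optimal
    gain/baseline/shift alignment of tachometric curves across subjects
    and pooling of their trial streams; a conditional-independence test of
    interaction between history variables (measured versus predicted
    accuracy for joint history sequences, with a reliability-gated slope
    summary); and a generative model of task sessions with tunable
    history-dependent biases for fixture generation and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
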