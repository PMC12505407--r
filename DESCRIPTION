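Package: digiphen
Title: Digital Phenotyping of Adolescent Mood from Smartphone Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a four-week adolescent digital-phenotyping
    deployment. Generates synthetic raw smartphone streams (GPS trajectories,
    screen lock/unlock logs, sleep intervals, lifestyle grids) coupled to a
    latent daily distress state; extracts the thirteen passive phenotypes
    (travel distance and time, location variance, location entropy and its
    normalised form, total/daytime/nighttime sleep, total/daytime/nighttime
    phone usage, lock duration, unlock frequency); schedules and aggregates
    ecological momentary assessments over eight daily prompt contexts; and runs
    the full statistical pathway: questionnaire scoring, interquartile-range
    outlier exclusion, pooled Pearson phenotype-EMA correlations, baseline
    group tests, 2x3 mixed repeated-measures ANOVA with Scheffe post hoc
    contrasts and Cohen's d on change scores, and noncentral-F power and
    sample-size calculations for repeated-measures designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
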