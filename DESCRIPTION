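Package: windcompass
Title: Simulation and Analysis of Airflow Encoding in Insect Central-Complex Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze experiments on directional airflow
    encoding in insect central-complex columnar neurons. Includes generators
    for whole-cell membrane-voltage recordings from direction-tuned model
    neurons, a closed-loop tethered-flight arena simulator with open-loop
    airflow perturbations, and two-channel calcium imaging traces with shared
    motion artifacts; plus analysis stages for spike detection, peristimulus
    time histograms, windowed stimulus responses, input resistance, circular
    tuning statistics, multisensory-integration similarity coefficients,
    closed-loop orientation and slip-correction metrics, ratiometric
    delta-F-over-F correction, and the nonparametric statistics used to
    summarize such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    tibble,
    dplyr,
    tidyr,
    withr,
    jsonlite,
    readr,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
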