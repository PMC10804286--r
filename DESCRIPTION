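Package: wbpsleep
Title: Breath-by-Breath Analysis of Rodent Whole-Body Plethysmography
    Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for breath-by-breath respiratory and metabolic phenotyping
    of rodent sleep recordings acquired by whole-body plethysmography with
    EEG/EMG and pulse oximetry. Converts chamber pressure to tidal volume via
    the Drorbaugh-Fenn barometric equation, segments airflow into breaths and
    extracts timing, volume and inspiratory flow landmarks, classifies
    inspiratory flow limitation, scores obstructive apneas and oxygen
    desaturations as per-hour indices by sleep stage, computes the
    hypercapnic ventilatory response slope, couples minute ventilation to
    open-circuit calorimetry (VO2, VCO2, RER) on an 11-minute grid, and
    provides exact nonparametric crossover statistics. A parameterized
    synthetic-recording generator supplies ground truth for every stage of
    the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    signal,
    data.table
Suggests: testthat (>= 3.0.0), knitr, optparse
Config/testthat/edition: 3
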