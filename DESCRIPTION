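Package: uihkit
Title: Analysis Toolkit for Ultrasound-Induced Torpor-Like Hypothermia Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of ultrasound-induced
    hypothermia and hypometabolism (UIH) experiments in rodents: automated
    brown-adipose-tissue temperature tracking in calibrated thermal video,
    windowed physiological endpoint extraction from core temperature and
    indirect-calorimetry traces, a closed-loop bang-bang body-temperature
    controller exercised against a simulated thermoregulatory plant, fiber
    photometry z-score and peak statistics, threshold-based in situ
    hybridization positivity quantification, and rule-based single-nucleus
    RNA-seq quality control and marker annotation. A synthetic-data module
    generates every input type with known ground truth so each stage is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    methods,
    jsonlite,
    yaml,
    readr,
    signal,
    tiff,
    Matrix,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
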