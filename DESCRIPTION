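Package: plantEIS
Title: Double-Shell Equivalent-Circuit Modelling of Plant Leaf Impedance Spectra
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for hourly electrical impedance spectroscopy (EIS)
    monitoring of plant leaves. Implements the five-element double-shell
    equivalent circuit (extracellular resistance, cytoplasmic and vacuolar
    resistances, plasma-membrane and tonoplast capacitances) as a forward
    model, replicate-sweep averaging, a derivative-free coordinate search
    with step-doubling line search that fits the circuit to measured
    frequency sweeps by minimising the summed absolute impedance error, and
    a time-series pipeline that tracks the fitted parameters across a
    watering and lighting schedule. A synthetic LCR-sweep generator
    reproduces the study design (four plants, hourly sweeps over sixteen
    hours, five replicates of a 201-point 500 Hz to 300 kHz sweep) so the
    whole pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, TimeCourse, Regression
RoxygenNote: 7.3.3
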