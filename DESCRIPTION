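Package: olivetools
Title: Quantitative Analysis of Inferior Olive Neuron Physiology, Morphology
    and Stereology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature extraction and design-based estimation for studies of
    inferior olive (IO) neuron hypertrophy and hyperexcitability. Provides
    intracellular spike analysis (dV/dt-based threshold, afterhyperpolarization
    and afterdepolarization measures, half-width, F-I curves), subthreshold
    oscillation (SSTO) quantification, passive membrane properties from
    current- and voltage-clamp steps, complex-spike identification in
    extracellular Purkinje-cell recordings, SWC-based single-neuron
    morphometrics including box-counting fractal dimension, optical
    fractionator and nucleator stereology with the Gundersen coefficient of
    error, and contingency-table gene-set enrichment with an exact
    hypergeometric test. A synthetic-data module generates every input with
    known ground truth so the whole pipeline is testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
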