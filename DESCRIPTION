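Package: sinedsc
Title: Perfusion and Cerebrovascular Reactivity Mapping from Sinusoidal
    CO2 BOLD MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cerebral blood flow, blood volume, mean transit
    time, vascular time delay and cerebrovascular reactivity from
    gradient-echo BOLD time series acquired during a sinusoidal end-tidal
    CO2 challenge. Deoxyhemoglobin acts as an endogenous susceptibility
    contrast agent: gradient-echo signal loss is converted to delta-R2*
    concentration curves, a venous output function is selected
    automatically, and tracer-kinetics deconvolution is carried out in the
    frequency domain at the fundamental stimulus frequency. Includes a
    digital phantom generator with known ground truth, a time-domain
    singular-value-decomposition deconvolution comparator, ROI
    summarization, and Bland-Altman/coefficient-of-variation agreement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
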