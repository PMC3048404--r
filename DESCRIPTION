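Package: gliomark
Title: Multiparametric MRI Biomarkers of Antiangiogenic Therapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of quantitative MRI biomarkers of
    anti-angiogenic therapy response in orthotopic mouse glioma: voxelwise
    T2/T2* relaxometry and steady-state susceptibility-contrast blood-volume
    mapping (rCBV/rMBV from iron-oxide-induced delta-R2* and delta-R2),
    relative vessel caliber index, apparent diffusion coefficient mapping,
    Tofts two-compartment DCE-MRI kinetic fitting with a fixed bi-exponential
    arterial input function, intravital-microscopy permeability, and
    longitudinal two-arm cohort statistics. Includes a digital mouse-brain
    phantom generator with forward signal models and Rician noise, calibrated
    group-effect profiles, and an end-to-end simulate-fit-summarize pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
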