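Package: dopaPET
Title: Reference-Tissue Kinetic Modelling of Dynamic 18F-DOPA PET
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for VOI-based kinetic analysis of dynamic 18F-DOPA
    positron emission tomography in small animals. Implements frame
    schedules and time-activity curves with SUV and SUVr computation,
    Patlak and Logan reference-tissue graphical analysis (influx rate
    constant Ki and distribution volume ratio DVR), the effective DVR
    (EDVR) obtained by reference-TAC subtraction together with effective
    dopamine turnover and left-right asymmetry endpoints, cohort-level
    group statistics (one-way ANOVA with Tukey HSD, paired t tests,
    quantile-quantile diagnostics), a closed-form linear compartment-model
    simulator with a tri-exponential bolus input for parameter-recovery
    validation, voxel phantom generation with VOI-based TAC extraction
    from 4D images, and in-silico restriction-digest genotyping utilities
    for the SNCA G51D rat model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, Biostrings, RNifti
Suggests: testthat (>= 3.0.0), deSolve, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
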