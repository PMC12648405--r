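Package: bprr
Title: Distance-Resolved Bipolar Re-Referencing Analysis for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how the physical distance between the two
    contacts of a bipolar re-referenced (BPRR) intracranial EEG channel
    reshapes its power spectrum, task-related high-gamma contrasts, and
    line-length based detection of interictal epileptiform discharges.
    Builds linear-ordinal and omnidirectional bipolar pair sets from 3D
    electrode coordinates, estimates multitaper spectra on 1 s windows,
    constructs distance-by-frequency maps (z-scored power and percent
    change from referential recordings), and runs cluster-based
    permutation statistics. Includes a synthetic multi-electrode field
    generator (traveling-wave continuum plus spatially coherent aperiodic
    activity and common-mode artifact) with closed-form oracles linking
    bipolar distance to power ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
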