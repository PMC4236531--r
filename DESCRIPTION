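Package: capgap
Title: Capability-Gap Analysis for Assistance-as-Needed Exoskeleton Sizing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the assistive joint moment and power a lower-limb
    exoskeleton must supply (the "capability gap") when muscle weakness is
    present, during activities of daily living. Solves a per-frame
    static-optimization muscle-redundancy problem with Hill-type muscle groups
    and costly ideal moment actuators (reserves) under an exact net-moment
    constraint, sweeps simulated weakness by uniform reduction of maximal
    isometric force, and contrasts the resulting assistance-as-needed sizing
    with classic inverse-dynamics sizing. Includes planar recursive
    Newton-Euler inverse dynamics, a synthetic activity-of-daily-living trial
    generator that is dynamically consistent by construction, an EMG-envelope
    processing and Spearman-correlation validation chain, and OpenSim-style
    STO/MOT and CSV readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
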