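Package: pcipos
Title: Phase Coordination Index and Point-of-Stabilization Detection for Gait Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes left-right stepping phases and the Phase Coordination
    Index (PCI) from heel-strike event times, and detects the point of
    stabilization (POS) of a cumulative PCI series: the stride count from
    which adding further strides no longer changes the PCI estimate
    appreciably. Detection uses a two-stage backward search with a
    coefficient-of-variation stability criterion over size-adapting moving
    windows (a consecutive-window and an evenly-dispersed-window option,
    combined by a maximum rule). Includes a stride-time and stepping-phase
    simulator for generating virtual participants, true/absolute error
    metrics against the trial-final PCI, POS-aligned error profiles, cohort
    summary tables, readers and writers for heel-strike and PCI tables, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse
Config/testthat/edition: 3
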