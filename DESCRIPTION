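Package: AxonVelocity
Title: Axonal Conduction Velocity Analysis for Microchannel-Coupled
    Microelectrode Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings of axons confined
    in PDMS microchannels aligned over microelectrode array (MEA) electrodes.
    Detects spikes from high-pass filtered voltage traces, detects bursts with
    MaxInterval-style criteria, extracts spikes that propagate across all
    electrodes of a microchannel to estimate axonal conduction velocity,
    analyses peri-stimulus evoked responses and their fidelity across trials,
    and correlates activity features with propagation velocity across modules
    and recording days. A synthetic-data module simulates the device (8
    reservoir modules, 5 microchannel electrodes at 200 um pitch) with known
    ground truth so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    data.table,
    arrow,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
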