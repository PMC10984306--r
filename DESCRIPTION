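Package: swdquant
Title: Quantification of Spike-and-Wave Discharges and Absence Status in Rodent EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify spike-and-wave discharges (SWDs) and
    absence-status epilepticus in two-channel rodent cortical EEG.
    Implements amplitude/frequency/duration-based SWD detection with a
    merge rule for near-contiguous discharges, classification of
    continuous discharges over one minute as absence-status events,
    delta-dominance scoring of sedation sleep, segmentation of a
    drug-injection session into baseline, initial status, sleep, and
    second status period, multitaper (DPSS) power spectral density and
    interhemispheric coherence on a 1-40 Hz grid, per-frequency
    Mann-Whitney comparisons with Benjamini-Hochberg false discovery
    rate control, and a homogeneity-of-variance test on per-cycle spike
    peak voltages. A phenomenological two-channel EEG simulator
    generates dexmedetomidine-like sessions with ground-truth
    annotations so every stage can be validated without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
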