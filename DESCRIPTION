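Package: barseqevo
Title: Barcode-Sequencing Analysis of Pooled Fitness Assays and
    Experimental Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for serial-transfer experimental evolution
    of barcoded yeast lineages tracked by amplicon sequencing. Demultiplexes
    dual-indexed barcode reads into sample-by-barcode count matrices,
    estimates per-sample barcode cross-contamination rates, computes
    Malthusian and Wrightian fitness from paired pooled competition assays,
    summarizes two-barcode lineage-dynamics trajectories (including
    fixation calls), fits the read-weighted linear and mixed models used
    for treatment-level inference, and provides noncentral t and F power
    calculations. A ground-truthed serial-dilution simulator generates
    complete synthetic studies (counts or FASTQ) for validation and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
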