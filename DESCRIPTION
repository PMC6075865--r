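Package: exokin
Title: Kinetic Analysis of Regulated Exocytosis: Capacitance Pools,
    Amperometric Fusion-Pore Statistics, SNARE Assembly Rates and
    Helix-Mimicry Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative workflows of chromaffin-cell
    secretion studies. Decomposes flash-photolysis evoked membrane
    capacitance responses into readily and slowly releasable pool
    components with a sustained rate and a secretory delay; detects
    amperometric spikes and quantifies main-spike kinetics, prespike-foot
    parameters, fusion-pore flicker frequency and rms noise with
    per-cell aggregation; fits the integrated second-order rate law to
    SDS-resistant SNARE complex assembly time courses and compares group
    rates by rank statistics; and scores SNAP25-SN1 mimicry of peptide
    segments by BLOSUM62 percent similarity, Eisenberg hydrophobic
    moment and helical-wheel projection. Seeded synthetic-data
    generators emulate each recording modality so every estimator can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, Proteomics
RoxygenNote: 7.3.3
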