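Package: natrace
Title: Fast Nucleic-Acid Backbone Tracing in Electron-Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates ribose and phosphate groups in crystallographic
    electron-density maps using fingerprint probe-point scoring with
    aggressive early termination, then grows the hits into nucleotide
    backbone chains using a conformer database built from a reference
    structure, with a calibrated stopping score, short-fragment
    filtering and trace merging. Includes a synthetic-data module
    (idealized A-form helices, Gaussian-atom maps, figure-of-merit
    driven phase-error degradation) and model-vs-reference coverage
    metrics, plus CCP4/MRC map and PDB input/output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
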