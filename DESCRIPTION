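Package: swathmarkers
Title: SWATH-MS Quantification QC and Candidate Kidney-Injury Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-extraction processing of SWATH-MS (DIA) transition-ion
    intensity tables: total-intensity (AUC) normalization, per-ion lower
    detection-limit exclusion, technical-replicate CV filtering, and
    hierarchical rollup of ion medians to peptide and protein areas.
    Downstream, proteins of differential abundance between study groups are
    identified with pairwise Welch tests and Benjamini-Hochberg adjustment,
    categorized by their abundance pattern across an acute decompensated
    heart failure time course (injury, recovery, long-term impairment),
    shortlisted against a biofluid-detectability (secretome) annotation, and
    flagged for prior acute-kidney-injury associations. Includes a synthetic
    ion-level data generator with ground truth for validating false-discovery
    control and detection power, and renal-physiology utilities (creatinine
    clearance, serial group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
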