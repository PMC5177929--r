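Package: stressmir
Title: Small RNA Workflow for Conserved miRNA Annotation and Stress
    Time-Course Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing workflow for plant stress
    time-course experiments: adapter trimming, 18-24 nt size selection,
    distinct-tag collapsing and RPM normalization, removal of
    ncRNA/chloroplast contaminants, annotation of conserved miRNAs from
    precursor loci with hairpin minimum-free-energy and star-sequence
    (2-nt 3' overhang) evidence, trimmed-mean normalization with
    negative-binomial generalized linear models over a treatment-by-time
    design, and plant-style miRNA target complementarity scoring.
    Includes a synthetic read generator that plants hairpin precursors,
    contaminants and stress effects with recorded ground truth so the
    whole chain is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    stringi,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
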