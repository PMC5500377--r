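Package: clonesv
Title: Somatic Structural Variants, Clonal Architecture and Mutational
    Signatures for Tumor Whole-Genome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A paired-end-cluster somatic structural-variant caller with
    four-way classification and panel-of-normals subtraction, copy-number-
    and allele-frequency-based inference of tumor clonal architecture
    (cellularity and clonality), a copy-number model for interhomolog
    inverted rearrangements, trinucleotide mutation-spectrum and
    signature-exposure summaries, and the cohort association statistics
    used in triple-negative breast cancer genomics. Includes a seedable
    synthetic-tumor generator so that every stage can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
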