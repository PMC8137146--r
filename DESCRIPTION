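Package: rtquant
Title: Quantifying Transcription Read-Through, PROMPT Stabilisation and
    Termination-Factor Screens from Stranded Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring failure of RNA polymerase II transcription
    termination from stranded coverage tracks: a read-through index
    contrasting signal downstream of the transcription end site against the
    gene body, strand-split metagene profiles, quantification of promoter
    upstream transcripts (PROMPTs) and their extension on factor depletion,
    polyadenylation-signal (AWTAAA) motif density, super-enhancer log-ratio
    metaplots with bootstrap confidence halos, exonic counting with TPM
    filters, a simple two-condition differential-expression caller, and the
    abundance-ratio filter used to select proximity-labelling candidates.
    Includes a seeded synthetic-data generator that plants every effect with
    machine-readable ground truth, so each statistic can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
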