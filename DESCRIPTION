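Package: wrkysurvey
Title: Genome-Wide Survey Toolkit for WRKY Transcription-Factor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for genome-wide surveys of
    the plant WRKY transcription-factor family: deterministic WRKY domain
    identification (heptapeptide variants plus C2H2/C2HC zinc fingers) and
    group/subgroup classification, chromosomal tandem-cluster detection from
    gene models, promoter cis-acting regulatory element (CARE) scanning with
    an editable IUPAC motif dictionary, Nei-Gojobori (1986) Ka/Ks estimation
    with Jukes-Cantor correction and synonymous-rate molecular dating,
    neighbor-joining phylogenies with bootstrap support and reference-guided
    subgroup assignment, and qRT-PCR 2^-ddCT fold-change analysis with signed
    fold-change regulation calls. Seeded synthetic-data generators produce
    every input with machine-readable ground truth, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    BiocGenerics,
    ape,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
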