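Package: methpatterns
Title: De Novo DNA Methylation Pattern Analysis from Bisulfite Clone Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how de novo DNA methyltransferases
    (DNMT3A/DNMT3B, with or without the DNMT3L stimulatory factor) choose
    their targets. Generates synthetic bisulfite clone reads from episome-like
    reference regions with planted flanking-sequence preferences, maintenance
    strand symmetry, dcm (CCWGG) strand tags and incomplete conversion; calls
    per-CpG methylation from gaplessly aligned clone reads with per-molecule
    conversion-efficiency filtering; computes per-site efficiency tables,
    rankings, hot/cold decile selection, positional chi-square flank
    enrichment with sequence-logo information content, strand-symmetry and
    DNMT3L fold-stimulation statistics; and scans sequences for word
    exceptionality under a first-order Markov background together with
    CpG-island metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
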