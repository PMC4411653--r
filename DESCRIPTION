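Package: pseaacvar
Title: Coding-Variant Deleteriousness Scoring with Amphiphilic Pseudo
    Amino Acid Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects genomic variants onto protein sequences, encodes the
    wild-type and mutant peptide snippets around the first changed residue
    as amphiphilic pseudo amino acid composition (PseAAC) vectors, and
    classifies variants as damaging or tolerated with a random forest (or
    logistic regression) trained on the PseAAC difference together with
    protein-length, variant-position and per-base evolutionary conservation
    features.  External PolyPhen2/SIFT predictions can be folded in through
    a threshold-standardization and majority-voting ensemble.  A synthetic
    data module generates toy genomes, gene models, labeled variants with a
    plantable hydropathy-shift signal, conservation tracks and mock external
    scores, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    vcfR,
    randomForest,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
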