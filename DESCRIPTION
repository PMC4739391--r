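Package: barcodeGauge
Title: Evaluation of Candidate DNA Barcode Loci in Congeneric Plants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate candidate DNA barcode loci (such as ITS2,
    rbcL, psbA-trnH, ITS and matK) for species discrimination within a
    plant genus. Implements quality filtering of GenBank-style sequence
    sets, pairwise and progressive alignment, Kimura 2-parameter
    distances with pairwise deletion, six inter/intraspecific divergence
    parameters, barcoding-gap profiles, Wilcoxon signed-rank locus
    comparisons, leave-one-out species identification by nearest-distance
    and local-alignment top-hit methods, neighbor-joining monophyly
    assessment, and detection of diagnostic homopolymers, tandem repeats
    and inversions. A sequence simulator for congeneric datasets with
    known divergences and planted diagnostic features supports end-to-end
    validation without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
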