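Package: draftweaver
Title: Reference-Assisted Improvement of Draft Bacterial Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for upgrading fragmented draft bacterial genome
    assemblies using related reference genomes: contig-end extraction and
    reference-mediated physical-gap candidate discovery via a self-contained
    seeded local aligner with Karlin-Altschul E-values, exact-overlap and
    shared-reference-gene contig joining, resizing of oversized N-runs against
    homologous reference sequence, unique k-mer anchoring for reference-guided
    scaffold reordering, multi-assembly congruency checking, unique k-mer
    synteny dot plots, windowed GC and GC-skew tracks, and position log-odds
    promoter-box profile training and scanning. Includes a deterministic
    synthetic-fixture simulator (genome, diverged reference, fragmented
    assembly, corrupted gap sizes, planted genes and motifs) with full truth
    tables, so every step is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
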