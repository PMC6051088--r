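Package: knmir
Title: Discovery and Characterization of Unannotated miRNAs in Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for discovering previously
    unannotated miRNAs in aligned small RNA-seq data and characterizing them in
    a paired tumour/normal cohort. Read stacks are assembled into candidate
    hairpin loci, scored by weighted base-pair maximization folding with
    dinucleotide-shuffle p-values and a Dicer-processing read signature, and
    passed through an auditable filter cascade (read support, rRNA/tRNA decoy
    overlap, folding p-value, duplicate removal, Karlin-Altschul homology
    E-values against known miRNAs, GC outlier removal). Retained loci are
    quantified, TMM-normalized, gated on expression, tested for paired
    differential expression with Benjamini-Hochberg correction, and assessed
    for survival association via tertile grouping and weighted log-rank
    (Gehan-Breslow-Wilcoxon) tests. Targets are predicted with a seed-weighted
    complementarity alignment plus nearest-neighbor duplex energies and a
    scrambled-sequence null, and aggregated target genes are tested for pathway
    over-representation. A synthetic-data module generates every input with
    planted ground truth so each stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings,
    IRanges,
    fgsea
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    edgeR,
    jsonlite
Config/testthat/edition: 3
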