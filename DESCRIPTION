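Package: annodiff
Title: Repertoire-Wide Structural Comparison of Automatic and Manually
    Curated Gene Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares automatically predicted and manually annotated
    protein-coding gene models across a whole annotation. Reads a genome
    assembly (FASTA) and two annotations (GFF3) together with a provenance
    map linking curated models to their automatic predecessors, partitions
    the models into the AUTO, OGS, AUTO-SUB, MAN-SUB and MAN-ADD
    (sub)sets, derives per-transcript structural properties from the
    longest transcript of every gene (unspliced length, protein length,
    exon and intron counts, per-transcript median exon/intron lengths and
    GC contents), and summarises and contrasts the sets with two-sample
    Kolmogorov-Smirnov and Wilcoxon tests (Bonferroni corrected), Spearman
    rank correlations of exon/intron count against length and GC, and a
    fixed-size subsampling procedure that classifies a subset's
    correlation coefficient as inside or outside the interval spanned by
    coefficients of repeated subsamples of the full set. A synthetic-data
    module generates genome, annotation, curated gene set and provenance
    files with known ground truth so the whole pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    dplyr,
    tibble,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
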