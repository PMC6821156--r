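Package: spliceQuant
Title: Annotation-Based Cataloguing and Coverage-Based Quantification of
    Alternative Splicing Events
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Catalogues the four classical alternative-splicing event types
    (skipped exon, mutually exclusive exons, alternative 5' and 3' splice
    sites) from a GTF annotation by pairwise transcript comparison,
    quantifies each event from RNA-seq coverage as the mean depth of the
    affected exon (n) against the remaining exons of its transcript (N),
    and calls differential splicing between two conditions with a 2x2
    Pearson chi-squared test filtered on P-value and inclusion-ratio
    difference. Also computes position-wise nucleotide frequency and
    certainty matrices for the -35..+5 window around 3' splice sites,
    reconstructs alternative 5'-UTR isoforms with upstream ORF scanning,
    and ships a seeded simulator (genome, annotation, two-condition
    coverage with known inclusion levels) so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
biocViews: AlternativeSplicing, RNASeq, Transcriptomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'coverage.R'
    'events.R'
    'gene-models.R'
    'quantify.R'
    'seqcontext.R'
    'simulate.R'
    'spliceQuant-package.R'
    'utils.R'
    'utr.R'
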