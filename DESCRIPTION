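Package: AnchorMap
Title: Genetic-Map Anchoring of Draft Assemblies into Pseudo-Chromosomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to turn draft genome contigs plus parental genetic linkage
    maps into validated pseudo-chromosome sequences. Marker probes are placed
    on contigs with a seeded ungapped aligner and filtered on percent identity
    and hit uniqueness; contigs are assigned to linkage groups by marker
    majority, chimeric contigs are detected from two-block marker patterns and
    split, and contigs are ordered and oriented from marker centimorgan
    positions, with the two parental maps integrated into a single anchoring
    plan. Pseudo-molecules are materialized with fixed N gaps and exchanged as
    AGP v2.1. Auxiliary computations include tandem-repeat (centromeric
    satellite) discovery and localization, k-mer spectrum genome-size
    estimation, windowed variant-density tracks, homozygous-SNP alignment
    export, and a truth-tracked synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: GenomeAssembly, Alignment, Sequencing, Annotation
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'AnchorMap-package.R'
    'agp-io.R'
    'anchor.R'
    'builder.R'
    'io.R'
    'kmer.R'
    'pipeline.R'
    'probemap.R'
    'repeats.R'
    'simdata.R'
    'stats.R'
    'utils.R'
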