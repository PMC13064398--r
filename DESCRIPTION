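Package: polysweep
Title: Selective-Sweep Scans for Polyploid SNP Dosage Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide detection of selection signatures from tetraploid
    (or general autopolyploid) SNP allele-dosage data. Computes per-locus
    observed and expected heterozygosity and unbiased nucleotide diversity
    from dosage calls, summarizes them in SNP-count and physical sliding
    windows as deviations from the genome-wide mean, attaches rank-based
    multiplicity-corrected simultaneous bootstrap confidence bands per
    chromosome, and calls candidate sweep regions with a within-group
    local-minimum/quantile caller and a two-group tail-cluster caller based
    on Fst, heterozygosity differences and nucleotide-diversity ratios.
    Includes gene-overlap annotation with Fisher exact term enrichment, a
    seeded synthetic panel generator with known injected sweeps for
    validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
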