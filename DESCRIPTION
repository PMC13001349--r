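Package: trbench
Title: Multi-Metric Evaluation of Tandem-Repeat Genotype Callsets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Benchmarking toolkit for tandem-repeat (TR) genotypes from
    long-read genotypers. Harmonizes heterogeneous TR-VCF dialects
    (sequence REF/ALT, symbolic length-only, consensus-appended) into a
    single allele model; derives truth genotypes from haplotype-resolved
    assemblies by projecting catalog coordinates through alignment CIGARs;
    pairs called and truth alleles to minimize total deviation and
    classifies each locus as Match, Off-by-1bp, Off-by-motif or Mismatch;
    evaluates trio Mendelian consistency with a minimum-Manhattan-distance
    transmission search; computes pairwise cross-tool consistency and
    sensitivity to known pathogenic repeat expansions; and generates
    seed-reproducible synthetic truth worlds (reference, catalog, diploid
    haplotypes, trios, alignments and error-injected callsets) so every
    evaluation stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    GenomicAlignments,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
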