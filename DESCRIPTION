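Package: haplalign
Title: Locus-Specific Haplotype Alignments and Phylogenies from Phased VCF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts a phased multi-sample VCF over a user-designated genomic
    region into a complete, gap-consistent multiple sequence alignment of
    every haplotype. Handles multiallelic INDELs, mixed SNP/INDEL loci,
    duplicate and overlapping variant entries, structural-variant exclusion
    (50 bp boundary), integration of unphased single genomes under a
    homozygous-only rule, and projection of outgroup sequences through
    reference-anchored pairwise (AXT) alignments. Emits FASTA and relaxed
    sequential Phylip alignments plus a neighbor-joining phylogeny in newick
    format, with optional wrappers for external maximum-likelihood engines.
    Includes a deterministic synthetic-fixture generator so the full pipeline
    can be exercised without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    ape,
    phangorn,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
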