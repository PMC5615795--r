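# haplalign

Locus-specific haplotype alignments and phylogenies from phased VCF.

Population resequencing projects publish their variation as phased
multi-sample VCFs, but locus-specific evolutionary analyses — haplotype
structure, balancing-selection signatures, cross-species comparison — need a
complete, gap-consistent multiple sequence alignment of every haplotype in
the cohort. haplalign rebuilds those sequences directly from the variant
calls: for a region `chrom:start-end` it edits the reference window once per
haplotype (the VCF genotype `a|b` assigns allele *a* to haplotype 1 and *b*
to haplotype 2, with 0 = reference and 1..n selecting among the ALT
alleles), places every insertion in a reserved block of gap columns sized by
the longest allele at that anchor, renders deletions as `-`, and emits
equal-length rows without any realignment step. A diploid cohort of 2504
samples becomes an alignment of 5008 haplotype rows.

On top of the core transform the package handles the awkward realities of
cohort VCFs:

* **INDEL/SV boundary** — insertions/deletions under 50 bp are integrated
  as gaps; anything at or above 50 bp, symbolic (`<DEL>`), or annotated
  `SVTYPE=`/`VT=SV` is excluded from the alignment and written to
  `log.txt`.
* **Complex loci** — mixed SNP/INDEL sites, the same locus reported on
  several lines, and overlapping deletions are all rewritten into one
  canonical multiallelic record (SNVs padded to INDEL form, alleles
  deduplicated, genotype indices remapped). An *insertion* overlapping
  another INDEL cannot be placed against the reference: the run aborts
  with a dedicated error before writing any alignment.
* **Unphased single genomes** (archaic-style) — only homozygous SNVs are
  integrated; their INDELs are reported to `Indels_<name>.txt`, never
  applied.
* **Outgroups** — reference-anchored pairwise alignments (AXT) are
  projected into the cohort's coordinates, keeping only columns where the
  human side is ungapped.
* **Trees** — bundled p-distance (pairwise deletion) + neighbor joining
  with deterministic tie-breaking, midpoint rooting, and optional
  RAxML/FastTree wrappers (GTR+GAMMA defaults); newick output.

A deterministic fixture generator (`fixture_spec()`, `simulate_inputs()`)
produces every input class — including the pathological ones — together
with independent truth sequences, so the whole pipeline runs and is tested
without any external data.

## Worked example

```r
library(haplalign)

# synthetic inputs: reference FASTA, phased cohort VCF (3 samples),
# an unphased archaic VCF and a chimp-style AXT alignment
fix <- simulate_inputs(fixture_spec(seed = 7, n_samples = 3), dir = "demo")

cfg <- run_config(fix$region, fix$reference, fix$vcf,
                  archaic = fix$archaic, outgroup = fix$axt,
                  tree = "nj", outdir = "demo_out")
run_pipeline(cfg)
#> <run_report> chr1:1-1000
#>   cohort: 3 samples -> 6 haplotype rows (8 total rows, 1012 columns)
#>   variants: 24 normalized [DELETION=7, INSERTION=5, MNP_SUBSTITUTION=3, SNV=14]; 1 SV logged; 0 skipped; 0 clipped
#>   archaic Altai: 4 SNVs applied, 3 het skipped, 2 INDELs reported
#>   outgroup panTro: 3 human-gap columns dropped
#>   outputs: demo_out/chr1_1-1000.fasta, demo_out/chr1_1-1000.newick
```

Reading the report: the 1000 bp window grew to 1012 alignment columns
because the cohort's insertion alleles reserved 12 gap columns; 24
normalized variants were integrated while 1 structural variant was excluded
to `log.txt`; the archaic genome contributed 4 homozygous substitutions
(3 heterozygous sites stayed at the reference base, 2 INDELs went to
`Indels_Altai.txt` instead of the alignment); projecting the outgroup
dropped 3 chimp-specific insertion columns. `demo_out/` now holds the
FASTA and relaxed-Phylip alignments (8 rows: 6 cohort haplotypes labeled
`S0001_hap1` ... `S0003_hap2`, plus `Altai` and `panTro`), the side
reports, and the neighbor-joining tree:

```r
tree <- ape::read.tree("demo_out/chr1_1-1000.newick")
ape::plot.phylo(midpoint_root(tree))
```

The same run from a shell:

```sh
inst/cli/haplalign run --region chr1:1-1000 --ref demo/reference.fa \
    --vcf demo/cohort.vcf --archaic Altai=demo/altai.vcf \
    --outgroup panTro=demo/chimp.axt --tree nj --out demo_out
```

Exit codes: 0 success, 2 input error, 3 overlapping-insertion abort.

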