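---
title: "From phased variant calls to haplotype alignments and phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From phased variant calls to haplotype alignments and phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplalign)
```

## The problem

Population-scale resequencing projects distribute their results as phased
multi-sample VCFs: for every variable site, each diploid individual carries
two allele indices ("a|b"), where 0 is the reference allele and 1, 2, 3, ...
select among the alternative alleles. Locus-specific evolutionary analyses —
haplotype networks, tests of balancing selection, cross-species
comparisons — instead need a *complete multiple sequence alignment* of every
haplotype over a region, usually together with outgroup sequences. haplalign
reconstructs that alignment directly from the VCF and the reference, without
any realignment step, and builds a distance-based phylogeny from it.

The transform is exact by construction: every haplotype row is obtained by
editing the reference window at its designated alleles, and gap columns are
introduced so that all rows keep identical length. The package's master
invariant — checked throughout the test suite — is *degap equivalence*:
removing the `-` characters from any rendered row must reproduce, byte for
byte, the sequence obtained by applying that haplotype's variants directly
to the reference window.

## The model of the alignment

**Column map.** Every reference base owns one alignment column. A variant
whose allele set contains insertions reserves an *insertion slot* —
`max(len(alt) - len(ref))` extra columns — immediately after the last base
of its (normalized) REF span. Total width is therefore
`window length + sum of slot widths`. Carriers write their inserted bases
left-aligned into the slot; all other rows (including the reference track,
unphased genomes, and outgroups) carry `-` across it. Slot columns are
*positional, not homologous*: two equal-length insertion alleles occupy the
same columns whether or not their sequences are related. This is the price
of refusing realignment, which would be both slow at 5008 rows and a source
of instability.

**Variant classes.** Following 1000 Genomes nomenclature, insertions and
deletions smaller than 50 bp are INDELs; events at or above 50 bp, symbolic
alleles (`<DEL>`, `<INS:ME:ALU>`), and anything annotated `SVTYPE=` or
`VT=SV` are structural variants. SVs are never integrated — breakpoints of
large events are too unreliable to place against a linear reference — but
they are written to `log.txt` so the region's full variation remains
visible. When a `VT`/`SVTYPE` annotation is present it wins over the length
rule; the 50 bp cutoff is applied only to unannotated alleles.

**Complex loci.** Three pathological shapes occur in real cohort VCFs and
are rewritten into one canonical multiallelic record per locus before any
rendering:

* *Mixed SNP/INDEL loci* — the SNV's REF is extended with reference bases
  to the INDEL's REF length, and its ALT receives the same suffix
  (`convert_snp_to_indel_form()`).
* *Duplicate entries* — alleles reported for one position on several lines
  are concatenated, deduplicated (first occurrence wins), and each line's
  genotype indices are remapped into the merged allele space
  (`merge_same_locus()`).
* *Overlapping deletions* — records with intersecting REF spans are merged
  over the union span, each allele padded with the flanking reference bases
  it lacks (`merge_overlapping_deletions()`).

One shape cannot be represented at all: an *insertion* overlapping another
INDEL's span involves sequence absent from the reference, so there is no
column to put it in. The pipeline aborts with a dedicated
`overlapping_insertion_error` (CLI exit code 3) before writing any
alignment output.

After merging, output spans are pairwise disjoint, so no within-haplotype
edit-ordering ambiguity can arise; this is asserted, not assumed.

**Unphased single genomes.** High-coverage archaic genomes are unphased, so
only homozygous non-reference calls are trusted as true differences:
homozygous SNVs (and same-length multi-base substitutions, applied per
column) are written into that genome's single row; heterozygous and missing
sites keep the reference base; INDEL records — whatever their genotype — are
reported to `Indels_<name>.txt` rather than integrated. This deliberately
trades a small underestimate of divergence (and any heterozygosity signal)
for never fabricating a haplotype phase. The synthetic archaic generator
emits its INDELs as homozygous calls, matching the extreme homozygosity of
the real genomes this pathway models.

**Outgroup projection.** Outgroup sequences enter through reference-anchored
pairwise alignments (AXT blocks). Only columns where the human side is
ungapped survive: at each covered reference position the aligned outgroup
character is taken (outgroup-side gaps stay gaps), outgroup-specific
insertion columns are dropped, and uncovered positions receive the fill
character. Dropping human-gapped columns means human-specific deletions can
hide outgroup divergence; the per-outgroup count of dropped columns is
reported so users can see how much alignment was discarded. All cohort
insertion slots are gap-filled, so outgroup rows always match the cohort's
column count, and neither archaic nor outgroup processing ever modifies
cohort rows or the column map.

## Tree construction

The bundled builder is deliberately distance-based: p-distances under
*pairwise deletion* (per pair, only columns where neither row has `-` or
`N` count) followed by Saitou–Nei neighbor joining. Pairwise deletion
matters here: with thousands of rows and INDEL slots, complete deletion
could erase most columns. Two determinism guarantees make outputs
reproducible: ties in the Q-criterion are broken by the lowest (row,
column) index pair, and a negative branch length is clamped to zero with
the deficit moved to its sibling edge. On additive matrices the tree's path
lengths reproduce the input exactly (the tests verify to 1e-9, and check
NJ's topology against both an independent implementation and a brute-force
least-squares enumeration of all three 4-taxon topologies). Midpoint
rooting — the conventional choice for cohort trees without a designated
outgroup — is provided for display and haplogroup analysis.

Maximum-likelihood engines (RAxML, FastTree) are available as thin
wrappers invoked with GTR+GAMMA defaults; when the binary is absent the
wrapper raises `engine_not_found` so callers can fall back to NJ. The
wrappers are conveniences, never required: with `tree = "none"` the
pipeline outputs the alignment alone.

## What the synthetic generator emulates — and what it does not

`fixture_spec()` + `simulate_inputs()` produce every input the pipeline
consumes. Defaults emulate the variant density of a typical ~1 kb human
locus: one SNV per ~80 bp, a handful of short INDELs (≤ 6 bp), occasional
multiallelic, duplicate-entry and overlapping-deletion loci, one structural
variant, archaic genomes with mostly homozygous calls, and an outgroup at
1.3% divergence (the human–chimpanzee genome-wide value). Each generator
also emits an independent truth record computed by direct string surgery,
which is what the degap-equivalence tests compare against — the truth
construction shares no code with the column-map/rendering path.

The generator is deliberately simple where realism does not affect the
transform being tested: sites are uniform ACGT (no GC structure or repeat
content), genotypes are drawn independently per haplotype (no linkage,
no population structure except the explicit two-haplogroup mode), and
tree-recovery fixtures evolve sites under Jukes–Cantor along a fixed
8-taxon tree with 0.05-substitutions/site branches at 2000 sites. Passing
tests therefore demonstrate the correctness of the *transform* — allele
bookkeeping, gap placement, projection, distances — on all the variant
shapes the format can express; they do not demonstrate robustness to
misaligned or low-quality real-world calls, which no generator of this kind
could certify.

Problem sizes used by the checks were chosen to exercise the published
cohort shape while staying quick: the full 2504-sample/5008-row build runs
on a 1 kb window; degap equivalence sweeps 50 seeds at 5 samples; topology
recovery uses 100 replicates of 2000 sites.

## Numerical and design choices

* **Coordinates** are 1-based inclusive (`chrom:start-end`, tabix
  convention), converted once at the I/O boundary.
* **Records starting upstream of the region** whose REF span reaches into
  it are skipped and counted (`skipped.txt`), never truncated: truncating
  would fabricate an allele the user's window does not cover.
* **Deletions crossing the right window edge** are clipped to the window
  and counted; clipping only ever shortens a REF span whose inside part is
  fully determined.
* **Missing genotypes** (`.`) render as the reference allele by default
  (the transform only edits where an allele is designated), with a
  missingness count in the run report; `missing_policy = "N"` masks the
  span instead.
* **Unphased heterozygous genotypes in the cohort VCF** are a hard error:
  per-haplotype reconstruction is undefined without phase. Unphased
  genomes belong on the archaic pathway.
* **Conflicting merges** — one haplotype carrying non-reference alleles
  from two records merged at a locus — error by default
  (`on_conflict = "error"`); `"first"` keeps the first record's allele and
  counts the conflict.
* **Phylip output** is relaxed sequential (`name sequence`, names written
  in full): haplotype labels like `HG00096_hap2` exceed the strict
  10-character field, and truncation would collide thousands of labels.
* **Insertion slots for merged multi-base REF spans** anchor after the
  last base of the normalized span. For plain VCF records (REF length 1)
  this is exactly the left-anchored convention; for merged records the
  choice is invisible to degap equivalence because slot columns are
  positional.
* **A record mixing SV and non-SV alleles** keeps its non-SV alleles; the
  SV alleles are dropped (logged), and calls that carried them become
  missing. An SV overlapping an INDEL never suppresses the INDEL.

## Known limitations

* Insertion-slot columns are not homologous; downstream per-column
  statistics should either ignore slot columns or treat them as presence/
  absence codings.
* Distances use p-distance, not a substitution-model correction; for the
  within-species divergences this tool targets the difference is
  negligible, but deep outgroup branches are compressed.
* `p_distance()` is quadratic in rows; for full 5008-row cohorts an ML
  engine via `run_external_tree()` is the practical choice, exactly as the
  original workflow intended.
* Structural variants are excluded wholesale; breakpoint-resolved SV
  integration is out of scope.
* The archaic pathway drops heterozygous information by design and may
  therefore underestimate archaic–modern divergence in regions with
  residual archaic heterozygosity.
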