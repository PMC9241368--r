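---
title: "TIP discovery, genotyping and population analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TIP discovery, genotyping and population analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipscan)
```

## The problem

Transposable element insertion polymorphisms (TIPs) — TE copies present in
some accessions of a species and absent in others — are a major, and often
overlooked, class of structural variation in crop genomes. Short-read TE
callers (MELT, SPLITREADER, TEPID and relatives) struggle with insertions
that are absent from the single reference they map against. The strategy
implemented here splits the problem in two:

1. **Discovery against a pan-genome.** Long-read assemblies of many
   accessions are compared pairwise; insertion/deletion calls whose inserted
   sequence is a TE copy become candidate TIP loci. Because every insertion
   is assembly-backed, the locus set is trusted.
2. **Genotyping with population-scale short reads.** Each locus is reduced
   to a small local reference — the TE plus up to 1 kb of flanking sequence —
   and each accession's reads are mapped against it. The mapping *pattern*,
   not a de novo call, decides the genotype.

The genotype codes follow the convention of the field: `CC` = insertion
present (homozygous), `GG` = absent, `CG` = heterozygous, `NN` = missing.

## TE classification: the 80–80 rule

An SV sequence is accepted as a copy of a library element when the best
local alignment reaches **80 % identity over aligned columns and 80 %
coverage of the SV sequence** (`classify_te()`, thresholds exposed as
`id_min`/`cov_min`). Design choices that the rule's usual statement leaves
open:

* **Coverage denominator.** Coverage is measured on the SV (query) side:
  the claim being tested is "this SV is a TE copy", not "this TE is fully
  present". A `reciprocal = TRUE` flag adds the subject-side requirement.
* **Merged hits.** Non-overlapping local hits of the query against the same
  element are merged into the identity/coverage totals, the way blastn users
  sum HSPs for fragmented old elements. Secondary hits must reach a minimum
  local score (16 by default) so random micro-matches cannot inflate
  coverage.
* **Ties** are broken by higher identity, then longer alignment, then
  lexicographic element id, making classification order-independent.

Alignment uses affine-gap local alignment (match +1, mismatch −2, gap open
−5, gap extend −2; a gap of length $L$ costs $5 + 2L$), delegated to
`Biostrings::pairwiseAlignment()`. With these scores a uniformly diverged
full-length copy stays aligned end-to-end as long as its identity exceeds
2/3, so the 80 % identity boundary — not alignment truncation — carries the
classification decision. That is why planted copies at 15 % divergence pass
and copies at 25 % divergence fail with coverage still near 100 %.

Genic context (`assign_genic_context()`) classifies a 0-based insertion
point as `CDS`, `intron`, `upstream2kb`, `downstream2kb` or `intergenic`
with precedence CDS > intron > upstream > downstream, strand-aware flanks of
2 kb, and nearest-gene-start tie-breaking. Positions inside a gene body but
in non-coding exon sequence (UTRs) are reported as `intron` ("gene-body
non-coding"): the four genic classes form a partition, and simulated gene
models rarely exercise UTRs. By default `collate_insertions()` keeps only
genic loci when gene models are supplied, since the method tracks TIPs in
gene regions; `keep_intergenic = TRUE` disables that.

## Locus collation

Per-reference SV calls are projected onto one anchor genome (a deletion in
the anchor is the same locus as an insertion carried by the other genome)
and merged when positions agree within `merge_window = 100` bp and
sequences reach `merge_similarity = 80` % identity over an alignment
covering at least that fraction of the shorter sequence. The longest
sequence represents the locus. The exact deduplication rule used across the
original 20 × 19 pairwise comparisons is not specified anywhere; this merge
rule is a declared stand-in, both parameters are exposed, and the operation
is idempotent and order-invariant (records are processed in a canonical
sort order with deterministic tie-breaks).

## Genotyping from mapping patterns

`build_locus_construct()` assembles `left flank + TE + right flank`
(flanks ≤ 1 kb, truncated at contig ends) and the companion **TE-absent**
construct `left flank + right flank`. Evidence is collected symmetrically:

* **Presence**: reads spanning either TE junction with ≥ `min_aln = 20`
  aligned bases on *both* sides, plus read pairs with one mate wholly in a
  flank and the other wholly inside the TE.
* **Absence**: reads spanning the flank–flank junction of the absent
  construct with the same two-sided anchoring, plus pairs with mates in
  opposite flanks whose implied fragment length is consistent with no
  intervening TE (within 4 SD of the genome-wide insert estimate, when one
  is available).

The two-sided ≥ 20 bp anchoring is deliberately stricter than a global
"alignment > 20 bp" filter: a soft-clipped read ending exactly at a junction
carries no information about what follows the junction, and symmetric
anchoring removes that false-positive mode.

Decision rule (`genotype_locus()`): presence evidence without absence
evidence gives `CC`; the reverse gives `GG`; when both classes reach their
thresholds (`min_presence = min_absence = 1` read by default — permissive,
matching the "one or two boundaries covered" reading, and exposed because 1
is noise-sensitive at realistic error rates) the call is `CG` when the
minority evidence fraction is ≥ `het_fraction = 0.2`, otherwise the
majority homozygote. `NN` is reserved for loci with *neither* class of
evidence: a call of "missing" in the face of strong one-sided evidence
would violate the meaning of the code. No published definition of the CG
criterion exists for this genotyping scheme; the minority-fraction rule is
this package's own and is the simplest one that is monotone in evidence.

### The built-in mapper

`map_reads()` is an exact 21-mer seeding mapper with local extension: three
seed offsets per read (both ends and the middle, so any single substitution
leaves at least two seeds intact), candidate placements verified by direct
comparison, and the placement trimmed to the maximal-scoring ungapped
segment under the same match/mismatch scores as the aligner (a band-width-0
banded extension). Because the read simulator models substitutions only —
indel errors would not change the genotype decision logic under test —
ungapped extension is exact for simulated data; externally produced gapped
alignments (e.g. bwa mem with `-T 20 -Y`) enter through
`read_sam_alignments()`, which applies the same minimum-alignment filter.
All co-optimal placements of a read are kept: a flank-only read belongs
equally to the present and absent constructs, and discarding one placement
arbitrarily would silently destroy pair evidence. Duplicate evidence is
counted once per read pair.

`insert_size_validate()` provides the independent check: on the TE-absent
reference, a pair straddling a carrier's insertion point shows an apparent
fragment of about `insert_mean + te_length` (e.g. 500 + 4819 ≈ 5319 bp for
a 4.8 kb element with 500 bp inserts), while non-carrier pairs sit near
`insert_mean`. Insert statistics are estimated robustly (median/MAD, ≥ 20
pairs required) so discordant pairs cannot inflate the estimate.

## Population analysis

* **MAF filter** (`maf_filter()`): presence/absence alleles, CG contributes
  one of each, NN excluded from the denominator; loci with MAF ≤ 0.05 are
  removed before distance, tree and PCA work.
* **Distance** (`pairwise_distance()`): mean allele mismatch over loci where
  both accessions are genotyped (opposite homozygotes 1, homozygote vs
  heterozygote 0.5). The published description of the distance step is a
  one-line mention of a Perl script; allele-sharing mismatch is the simplest
  PHYLIP-compatible choice, and trees are of accessions over TIP loci.
* **NJ** (`nj_tree()`): Saitou–Nei via `ape::nj()`; negative branch lengths
  are clamped to zero with the deficit moved to the sister edge, preserving
  tip-to-tip path lengths.
* **PCA** (`tip_pca()`): dosages 0/1/2, centered at `2p`, scaled by
  `sqrt(2p(1-p))` (the plink convention), missing imputed to the locus
  mean, monomorphic loci dropped; eigendecomposition of the accession
  covariance; each component's sign fixed so its largest-magnitude loading
  is positive.
* **Selection scan** (`enrichment_scan()`): per locus a 2 × 2 table of
  carriers (CC or CG — presence of at least one insertion allele) vs
  non-carriers in a derived and a control group, NN excluded. The two-sided
  Fisher p-value is computed exactly in log space
  (`fisher_exact_2x2()`: sum of hypergeometric point probabilities not
  exceeding the observed one, relative tolerance 1e−7), so p-values near
  1e−80 are exact rather than underflowed. `-log10 p` is z-scored across
  all loci of the scan — the normalization population is the genome-wide
  locus set of that one scan, all-zero when the sd is zero. No
  multiple-testing correction enters the ranking; the scan reports raw p.
* **Core-variant comparison** (`core_variant_comparison()`): per gene, the
  smallest-p TIP and smallest-p nonsynonymous SNP; genes with both enter a
  paired two-sided t-test on raw p-values (matching the "average p-value"
  summary this comparison is built around), with a `log10 = TRUE` variant;
  genes lacking SNPs are reported separately; zero-variance differences are
  flagged degenerate instead of producing a misleading statistic.

## The synthetic-data generator

The simulator emulates the study design at desk scale: a base genome stands
in for the anchor assembly, donor genomes equal the base with planted TE
copies spliced in (length conservation is exact and tested), paired-end
reads are drawn with Normal insert sizes and optional substitution errors,
and matrix-level designs plant group-enriched loci (0.80 vs 0.02 carrier
frequencies across 329 + 195 accessions, mirroring a strong domestication
contrast) among neutral loci. Defaults throughout are the study's operating
points: 80/80 thresholds, 1 kb flanks, ≥ 20 bp alignments, MAF 0.05,
20× coverage, 150 bp reads, 500 ± 50 bp inserts.

What it deliberately does **not** model: TE nesting, LTR structure (target
site duplications, paired LTRs), recombination, demography, indel
sequencing errors, and reference bias from a real short-read mapper.
Passing tests therefore demonstrate the correctness of the decision logic
and statistics, not robustness to every artefact of real resequencing data.

Heterozygous carriers are simulated by mixing reads from carrier and
non-carrier haplotypes 50:50, which is exactly the situation the CG rule
must recognise; no published generative definition of CG exists for this
scheme.

### Problem sizes used by the tests

The bundled presets are `tiny` (3 loci × 6 accessions; smoke tests),
`demo` (50 loci × 60 accessions on a 125 kb base genome, 3–6 kb TEs,
error-free 20× reads; the genotyping-recovery benchmark, where recovery of
truth genotypes is ≥ 99 % with ≤ 1 % missing) and `scan_only` (500 loci ×
524 accessions; 100 seeded replicates of the scan recover all five planted
loci as the five smallest p-values). Genome-scale counts from real data
(tens of thousands of loci across 20 assemblies and 524 resequencing runs)
are out of reach of a test suite and are not asserted; the worked examples
that are asserted use the printed count tables directly.

## Numerical choices and degenerate inputs

* Alignment scores are integers; the DP oracle used in tests reproduces the
  gap convention exactly (gap of length $L$ costs $5 + 2L$).
* `fisher_exact_2x2()` treats a zero margin as p = 1 with a warning.
* `enrichment_scan()` skips (with a warning) loci with no genotyped
  accession in a group rather than fabricating a table.
* `nj_tree()` requires a symmetric zero-diagonal matrix and at least three
  taxa; ties in the Q-criterion are resolved deterministically by `ape`.
* All simulation entry points take an explicit seed and restore the
  caller's RNG state; identical configuration + seed reproduces outputs
  byte-for-byte, including FASTQ files.
* Every `run_pipeline()` output is attributable to a logged configuration:
  the effective parameters (no hidden defaults) are echoed into `run.log`
  and `manifest.json` together with output checksums.

## Known limitations

Classification reports only the single best library element; nested or
chimeric TEs are out of scope. The collation merge rule is a stand-in (see
above). The built-in mapper is not a general-purpose aligner — it is exact
for substitution-only reads and should be replaced by the SAM path for real
data. The paired t-test on raw p-values inherits the usual criticism that
p-values are not effect sizes; the −log10 variant is one flag away.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- preset_config("tiny")
fx <- build_population_fixture(cfg, seed = 1)
cl <- classify_sv_table(fx$pangenome$sv, fx$library)
loci <- collate_insertions(cl[cl$classified, ])
cons <- lapply(seq_len(nrow(loci)), function(i)
  build_locus_construct(loci[i, ], fx$pangenome$base))
gp <- genotype_population(cons, fx$reads)
table(gp$codes, ifelse(fx$pangenome$truth$carriers, "CC", "GG"))
```
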