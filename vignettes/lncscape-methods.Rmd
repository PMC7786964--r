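---
title: "Methods: lncRNA identification and characterization in lncscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification and characterization in lncscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures the package
implements, the parameters that matter and their defaults, the design
of the synthetic-study generator, and the numerical conventions that
make the test suite exact. It states no empirical result beyond what
the tests and `scripts/acceptance.R` themselves compute.

## Coordinate and strand conventions

All internal arithmetic is 1-based inclusive (the GTF convention). The
only 0-based, half-open input is the BED-style TE track, converted at
the reading boundary (`read_te_track()` adds 1 to starts). A
transcript's span is `[min exon start, max exon end]`; introns are the
gaps between consecutive exons. Unstranded (`.`) transcripts are
accepted at parse time but excluded from classification with a
warning, because every retained class code is strand-defined.

The GTF reader and writer are implemented in the package so that
malformed lines are reported with their line number, transcripts
declared without exons are an error, an empty file yields an empty
annotation with a warning, and `read_gtf(write_gtf(x))` reproduces `x`
byte-stably after normalization. Interval queries go through
GenomicRanges; FASTA and sequence manipulation through Biostrings.

## Genomic-context classification

The classifier reproduces the subset of gffcompare semantics the
filtering recipe relies on, with an explicit precedence per
transcript:

1. any same-strand exonic overlap with any reference transcript ->
   `sense` (collapsing `=`, `j`, `c`, `o`, ...; these are only ever
   excluded, so the distinctions are irrelevant here);
2. otherwise any opposite-strand exonic overlap -> `x`;
3. otherwise containment of the whole span within a single reference
   intron, on either strand -> `i`;
4. otherwise `u`.

Intron containment is tested on either strand: since `x` is defined by
exonic overlap only and exonic overlap has already been ruled out at
step 3, the three retained codes stay mutually exclusive. Different
gffcompare builds disagree on whether `i` is same-strand only; the
either-strand choice here is deliberate and documented rather than
guessed, and the classification is oracle-tested against a brute-force
all-pairs enumeration.

The reference annotation is assumed to contain protein-coding genes
only, so overlap with *any* reference transcript triggers exclusion.

## The filter cascade

Thresholds (all defaults in `filter_criteria()`): minimum spliced
length 200 nt, minimum 2 exons, maximum ORF 299 nt, minimum RPKM_max
1.0. Coding-evidence verdicts (CPC, CNCI, BLASTX vs SwissProt, Pfam;
all at E = 1e-3) are produced by external tools and consumed as
tables; a transcript absent from the evidence table counts as having
no evidence of coding. A transcript flagged by *either* CPC or CNCI is
removed — "no or weak coding potential by CPC and CNCI" is read
conjunctively on the clearing side.

ORF convention: the longest reading frame starting at ATG in any of
the three forward frames of the sense-strand spliced sequence; the
stop codon counts toward the length, and an ORF lacking an in-frame
stop extends to the last complete codon and still counts. This is the
conservative choice for discarding possibly-coding fragments, and it
is stated precisely so the exhaustive start/stop-scan oracle in the
tests can be exact. Codons containing N are neither starts nor stops.

All six predicates are evaluated for every candidate, so the survivor
set is provably invariant to the order of the four independent
evidence filters (b–e); the stage report counts survivors in the
canonical order a–f. `RPKM = 1e9 * C / (N * L)` with the per-sample
maximum taken after the per-sample RPKM computation. Composition
percentages are rounded half-up to two decimals (base R's round-half-
to-even would print 2.84 where the field's reports print 2.85).

## Tissue specificity

Expression profiles are replicate-averaged mean RPKM per group,
computed on the linear scale. The Jensen-Shannon specificity score of
a profile normalized to a probability vector `p` is
`max_t [1 - sqrt(JSD(p, d_t))]` over one-hot indicator distributions
`d_t`, with base-2 entropy, so the score lives in [0, 1], equals 1
exactly on one-hot profiles and is minimal on uniform ones. The tau
index is `sum(1 - x_i/max_j x_j)/(n - 1)`. Both are computed on linear
RPKM; much of the benchmark literature log-transforms before tau, so
that is left to the caller (transform the profile first if desired).
Both scores are scale-invariant, which the tests assert as a property.

All-zero profiles have undefined specificity and are reported missing
and excluded from distributions. Expression tiers split at RPKM_max
5.0 and 50.0, with both boundaries belonging to the upper tier. The
threshold for calling a gene "highly tissue-specific" is not a settled
community constant; the default is a JS score of 0.95 (inclusive),
configurable, and downstream counts are treated as descriptive rather
than as reproduction targets.

## Statistical kernels

All tests are two-sided and surfaced as `(statistic, p, method)`. The
Wilcoxon rank-sum test is exact (by enumeration, via the null
distribution) when the combined sample size is at most 20 and there
are no ties, and otherwise uses the tie-corrected normal approximation
without continuity correction — the threshold is fixed and there are
no hidden toggles. Fisher's exact test returns the conditional
two-sided p (sum of hypergeometric probabilities no larger than the
observed table's) and reports the sample odds ratio `ad/bc`; a table
with a zero margin carries no information and returns p = 1 by
convention. The chi-squared test uses no continuity correction. GO
enrichment is the hypergeometric upper tail per term over the
background universe, BH-adjusted across all tested terms, significant
at q < 0.05. Every exact mode is tested against an enumeration or
binomial-coefficient oracle on small instances.

## Conservation and synteny

BLAST tabular files (outfmt 6) are summarized at the two standard
cutoffs, 1e-3 and 1e-10, counting each query once regardless of hit
multiplicity; the relative decrease between cutoffs is
`100 (n_loose - n_strict)/n_loose`, half-up at two decimals.

For synteny, a locus' neighbourhood is the 3 nearest PCGs strictly
left and 3 strictly right of its span by genomic coordinate,
strand-agnostic; a PCG overlapping the locus is assigned to the side
of its midpoint. A cross-species pair is accepted iff the two
neighbourhoods share at least 3 distinct ortholog groups (tandem
paralogs collapse to one group, preventing paralog inflation) and, in
each species separately, the shared groups include at least one gene
from the left list and one from the right list. Because the side
requirement is evaluated per species, a locally inverted block still
qualifies; setting `side_consistent = TRUE` additionally requires a
shared group on the left in both species and one on the right in
both. Families are the connected components of the accepted-pair
graph; singleton loci belong to no family.

## Neighbour pairs and cis candidates

Pairs are formed at the locus level between an anchor and every PCG
whose span intersects it or lies within 10 000 bp (span gap, inclusive
at the boundary); overlapping pairs get distance 0 and keep their
orientation stratum (same/opposite strand). The PCG–PCG control is
computed genome-wide by the same function with self-pairs excluded.
Correlations are Pearson on replicate-averaged group-mean RPKM over
all 14 groups — the same vectors the specificity scoring uses; pairs
with a zero-variance member are excluded rather than given an
arbitrary value. Cis candidates require `|PCC| > 0.5` strictly.

## The synthetic-study generator

The generator emulates the downstream structure of a multi-tissue
insect RNA-seq study: 14 sample groups (9 tissues — accessory gland,
male/female antennae, testis, ovary, male/female head, male/female
midgut — and 5 developmental stages), 21 samples in total with two
replicates for seven of the tissues and none for the antennae and
stages. Its defaults are fixed study conditions, chosen once:

* **Genome/annotation geometry.** One PCG per 10-kb slot (3 exons,
  alternating strands), chromosomes of 40/30/20 slots so lncRNA
  counts co-vary with chromosome size. Candidates are planted at
  fixed in-slot offsets whose true class is known by construction:
  intergenic, intron-contained, antisense-exon-overlapping, plus
  same-strand decoys, < 200 nt decoys, trace-abundance decoys
  (RPKM 0.0005–0.005, far below the filter boundary because count
  discreteness at ~0.5 RPKM would otherwise let two reads in one
  sample clear RPKM_max >= 1), and coding decoys carrying a planted
  396-nt ATG ORF and cycling through the five evidence signatures
  (CPC only, CNCI only, BLASTX only, Pfam only, all four).
* **ORF-free sequence.** Planted noncoding exons are written into the
  genome as random sequence interleaved every <= 70 nt with a 22-nt
  motif that contains stop codons in all three frames and equals its
  own reverse complement, bounding any ORF on either strand well
  below 300 nt even across splice junctions.
* **TE track.** Records are placed deterministically inside exons of
  the first half of the lncRNAs and 40% of the PCGs (fractions
  configurable and exact), in positions that cannot touch any other
  feature's exons, with class labels cycled through LINE, SINE, LTR,
  DNA, RC/Helitron, Unknown.
* **Expression.** Mean-RPKM profiles per feature: housekeeping
  (log-normal base, 15% group jitter), tissue-specific (one dominant
  group near 80 RPKM over a 0.3-RPKM floor), testis-/ovary-dominant
  (60 vs 0.3), and trace decoys. Counts are negative-binomial around
  `RPKM * L * N / 1e9` with dispersion 0.05 and 2e6 mapped reads per
  sample; dispersion 0 gives deterministic rounded means, which the
  tests use as a degenerate-limit check. The testis-vs-ovary DE table
  is derived from the planted profiles, so bias calls are exactly
  recoverable.
* **Cis pairs.** Half of the intergenic lncRNAs share a latent
  profile `z ~ N(60, 40)` (truncated at 0.5) with their nearest PCG;
  both members observe `z` plus independent Gaussian noise scaled so
  the population Pearson correlation equals the target (0.8 by
  default). Planted intergenic loci sit at least 3 gene slots apart
  because the 3-flanking-gene synteny rule genuinely links closer
  loci, which would blur the planted family truth.
* **Second species.** Gene order inside two 10-slot blocks per
  chromosome is preserved with 1:1 orthologs; the remaining genes are
  reversed and stride-interleaved across the second species so no
  rearranged gene keeps a conserved neighbourhood. A u-locus is
  planted as syntenic iff its flanks reach conserved genes on both
  sides (slot < last conserved slot); loci in rearranged regions get
  a cross-species counterpart whose neighbourhood cannot satisfy the
  side rule.
* **GO.** Every PCG draws 3 of 40 background terms uniformly; one
  planted term is concentrated on the partner PCGs of the correlated
  pairs plus three background genes.

What the generator does *not* emulate — and hence what passing tests
do not establish about real data: read-level noise and mapping
artifacts (counts are drawn at the feature level), assembly
fragmentation and mis-assembled transcript models, overlapping or
nested PCGs, alternative isoforms per locus, unbalanced library
sizes, batch effects, and lncRNA sequence evolution (conservation is
planted through gene order, not sequence similarity). Recovery being
exact on the fixture demonstrates the correctness of the pipeline's
logic under its stated contracts, not the biological error rate of
the recipe on real transcriptomes.

## Problem sizes and determinism

Everything is a deterministic function of the seed: the same
`sim_config(seed)` regenerates byte-identical studies, and the
pipeline rerun on the same inputs writes identical tables. The default
fixture uses 3 chromosomes, 90 PCGs and 72 candidates, sized so the
full test suite and the acceptance script each complete in seconds
while every planted signal stays comfortably clear of its decision
boundary; the specificity and cis-pair recovery properties use 500
genes per class and 200/400 pairs respectively, large enough that the
binomial noise of the measured rates is small against the asserted
bounds.

## Known limitations

* Monoexonic lncRNAs are out of scope by construction (criterion a),
  as in the poly(A)-selected studies this pipeline mirrors.
* The classifier handles the three retained codes plus a collapsed
  `sense`; it is not a full gffcompare replacement.
* BLAST, CPC/CNCI, Pfam, OrthoMCL and DE model fitting are consumed
  as tables, never executed.
* With very small group counts (n < ~5) the Pearson p-values attached
  to pairs are fragile; the cis threshold operates on the correlation
  itself, not its p.
* The synteny family count over *all* loci can be smaller than the
  number of planted conserved u-loci: intronic/antisense loci lying
  inside a planted locus' gene neighbourhood are genuinely accepted
  by the rule and merge into that locus' family.
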