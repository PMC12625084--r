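---
title: "Methods: gene-family characterization with genefamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization with genefamr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamr)
```

genefamr implements the analysis arc of a plant gene-family study — census,
nomenclature, expression correlation, allele mining, promoter enrichment,
and synteny networks — as composable tibble-in/tibble-out functions. This
vignette records the models behind each stage, the tunable parameters and
their defaults, the design choices made where the method was genuinely
open, and what the synthetic-data tests do and do not demonstrate.

## Family census

A candidate protein joins the family iff it has at least one domain hit at
e-value ≤ 1e−5 for **every** required domain (default: a synthase-like and
a phosphatase-like domain, both configurable). Requiring all domains, not
any, is what separates true bifunctional-architecture family members from
single-domain relatives; an empty required set is an error because it would
silently retain everything.

Molecular weight is the sum of average (isotope-abundance-weighted)
residue masses plus one water, reported in kDa. The isoelectric point
solves net charge = 0 for the Henderson–Hasselbalch sum over the two
termini and the seven ionizable side chains. The shipped pKa set is
Bjellqvist-style (N-terminus 7.50, C-terminus 3.55; K 10.0, R 12.0,
H 5.98; D 4.05, E 4.45, C 9.0, Y 10.0); alternate tables can be passed to
`protein_pi()`. Because net charge is strictly decreasing in pH, bisection
on [0, 14] converges unconditionally; the tolerance is 1e−4 pH units.
Ambiguous residues (X, B, Z) are an error in strict mode and are skipped
with a warning in lenient mode — a documented choice, since any numeric
treatment of an unknown residue is an invention.

Site counts use canonical PROSITE patterns (CK2 `[ST]-x(2)-[DE]`, PKC
`[ST]-x-[RK]`, TYR `[RK]-x(2,3)-[DE]-x(2,3)-Y`, cAMP/cGMP `[RK](2)-x-[ST]`,
amidation `x-G-[RK]-[RK]`, N-glycosylation `N-{P}-[ST]-{P}`), counted over
all start positions with overlaps allowed (lookahead matching). Published
census tables of this kind do not always state whether high-probability
patterns were excluded during scanning, so printed per-protein counts are
not used as test oracles; the counting machinery is instead verified
against a brute-force interpreter of the PROSITE syntax on random
peptides.

## Ortholog nomenclature

Distances are p-distances — mismatches over aligned columns, excluding any
column where either row carries a gap. Each query receives the stem of its
minimum-distance reference; queries sharing a reference get suffixes
`.1, .2, …` by ascending distance. Published suffixes could in principle
also follow genomic position; distance ordering is implemented because it
matches the stated "relative similarity" reading, and every tie (equal
distance to two references, or equal suffix-ordering distances) is broken
lexicographically **and flagged** in the output so a reader can audit the
arbitrary choices.

The tree stage is neighbor joining on the same distance matrix (via ape),
with negative branch lengths clamped to zero. Maximum-likelihood inference
is deliberately out of scope: the nomenclature consumes only the distance
matrix, and the cluster memberships used downstream are recoverable from
distances. `tree_clusters()` cuts the k−1 longest internal edges and
reports connected components — a deliberately simple stand-in for clade
assignment that is exact on clean, additive data. Alignment construction
is likewise consumed, not performed; equal-length sequences (as emitted by
the generator for paralog pairs) pass through as a trivial gap-free
alignment.

## Expression correlation

Pearson r on raw TPM by default (log2(TPM+1) optional; published methods
of this kind rarely state a transform, and the choice is exposed rather
than hidden). p-values are two-sided from `t = r·√((n−2)/(1−r²))` with
n−2 degrees of freedom; the implementation computes the transform itself
and is cross-checked against `cor.test` in the tests. Constant expression
vectors have undefined r and are reported as missing — never coerced to
zero, which would fabricate evidence of independence. Replicates stay
separate samples. Significance defaults to α = 0.05 uncorrected, with an
optional BH column, since correlation-panel figures in this literature are
typically shown unadjusted.

## Allele mining

Variant records keep QUAL ≥ 30 and DP ≥ 5, both bounds inclusive; records
missing either field are dropped with a counted warning. Haplotype tables
are expressed in gene-relative coordinates: +1 is the first base of the
start codon on the coding strand, −1 the immediately upstream base, with
no position 0 — the signed convention of published per-gene haplotype
tables. On minus-strand genes, upstream means larger genomic coordinates
and alleles are complemented into coding orientation. The transform
round-trips exactly (property-tested on 1,000 random gene models of both
strands).

A row is **trait-specific** iff all group-1 alleles are identical, all
group-2 alleles are identical, and the two group alleles differ. The
printed deletion symbol `-` is a comparable allele (the studies that use
this representation call such rows indels); a distinct `.` denotes a
missing call and disqualifies the row. Multi-base indels are represented
one row per base at consecutive positions, matching the printed-table
convention. Heterozygous diploid calls are outside the printed single-
allele representation and are treated as missing.

Consequences: negative positions are promoter/upstream; genic positions
outside every exon are intronic; exonic substitutions are mapped through
cumulative exon lengths to a CDS offset, the codon `ceiling(cds_pos/3)` is
mutated, and the effect read off the standard genetic code, reporting
`Gly782Val`-style changes. Exonic indels whose length is not a multiple of
3 are frameshifts. The annotator is verified against an independent
whole-CDS-translation oracle on 1,000 random substitutions. The stability
report is arithmetic on externally computed potential energies
(`delta = e_mut − e_wild`) with a ±0.5 kcal/mol neutral band — published
tables label a −7.03 kcal/mol difference "Stabilizing" without stating a
threshold, so the band is explicit and configurable here.

## Promoter enrichment

Promoters are the 2,000 bp upstream of the start codon, strand-aware,
truncated at chromosome edges; windows shorter than 500 bp or with more
than 1,500 ambiguous bases are excluded with a logged reason, and the
retained+excluded counts always reconcile to the gene total.

Per-sequence motif score is the **affinity**: the mean over both strands
and all start positions of the per-window odds product
`∏ₖ M[k, base]/π[base]`, with ambiguous bases contributing odds 1. The
log of this mean-odds score is approximately normal across promoters,
which is exactly the "log-normal background" framing the enrichment test
needs; alternatives (best-window score, length-binned backgrounds) exist
in the literature, and the choice is isolated behind `pwm_affinity()`.
Because every retained promoter here is 500–2,000 bp and the vast
majority are full-length, no length-stratified correction is applied.

Backgrounds are per-motif (μ, σ) of ln affinity over **all** promoters
(the family's own promoters included, matching the genome-wide framing);
zero scores are floored at the motif's smallest positive score × 1e−3
before the log, so the fit stays defined without being dominated. The
family set is tested with `z = (mean ln A − μ)/(σ/√n)`, upper-tail normal
p, BH-adjusted, flagged at q ≤ 0.1. A degenerate σ = 0 background yields
p = 0 or 1 by the sign of the mean difference. Presence calls for
universally present motifs use a window hit threshold of 85% of the
motif's maximum achievable log-odds (configurable) — scanning tools used
for published per-promoter presence calls rarely publish their threshold,
so it is explicit here. The inner scoring loop is C++ (Rcpp), with a
plain-R reference scorer kept as the in-test oracle.

PWM collections are read from JASPAR-style count blocks (+0.8 pseudocount
per cell) or TRANSFAC-like probability blocks, both renormalized per
position.

## Synteny and networks

Gene rank indexes number genes 0..n−1 along each chromosome by start
coordinate. Anchors are homolog hits filtered to e ≤ 1e−5 and the top 5
per query; tandem-array anchors (same partner gene, ranks within the
overlap window) collapse to the best-scoring one (configurable off);
intra-genome hits are canonicalized so mirrored pairs coincide, and
self-hits are dropped. Chaining is dynamic programming over anchors
sorted by genome-A rank: a transition needs rank gaps in [1, max_gaps+1]
in both genomes and a consistent genome-B direction; the chain score is
`match_score·size + gap_penalty·(intervening genes)` with the published
parameter values (50, −1, size ≥ 5, max gaps 25, overlap window 5) as
defaults. Maximal-score chains are emitted greedily; score ties prefer
the longer chain; leftover anchors within the overlap window of an
emitted block are absorbed by it rather than spawning duplicates. The
original tool's internal block e-value is unpublished and is not
reproduced; block retention is size ≥ match_size with positive score.
Equivalence with an exhaustive chain search is asserted on 500 random
instances of up to 12 anchors.

Gene collinearity networks take family genes appearing in retained blocks
as nodes and direct anchor pairs as edges; connected components are the
clusters. Published network figures describe edges as "syntenic
relationships", which reads most naturally as direct anchor pairs; a
`co_membership = TRUE` flag additionally connects family genes that share
a block, which is what groups whole duplication events into single
components. QTN proximity reports gene–locus pairs within 1.0 Mb
(inclusive), distance 0 inside the gene span, locus ids parsed as
`<chromosome>_<position>`.

## Synthetic data: what it emulates, what it does not

The generator is the package's test bed and emulates the study shape: ~5
chromosomes × 200 genes; an 18-member family arranged as 9 paralog pairs
planted inside 4 duplicated segments (two plus, two minus orientation) —
the whole-genome-duplication signature the census and synteny stages are
meant to recover; two phenotype groups of 2 accessions; 3 planted
trait-specific SNPs among 50 rule-violating random variants; one promoter
motif inserted at rate 0.8 in family promoters vs 0.05 genome-wide, the
regime in which a real enriched element separates cleanly from background;
GC content 0.40. Family proteins are 820–970 residues, matching the
published family's range, and carry two fixed signature peptides that the
domain-hit table keys off — a deliberate stand-in for profile-HMM search,
which is out of scope. Gene structure is fully consistent: proteins are
reverse-translated with a fixed codon table, split into 1–3 exons, and
embedded in the chromosome sequence, so promoter extraction, coordinate
transforms, and consequence annotation run against real sequence, not
mocks.

One global seed drives one documented RNG stream per output type (genome,
variants, expression, motif planting, PWMs), so adding an output never
shifts an existing one and identical configs give byte-identical files.

What the generator does **not** emulate: read-level data and sequencing
error, realistic codon usage and intron/intergenic composition, linkage
between variants, tandem gene arrays, partial domain decay, or motif
instances sampled away from the consensus. Passing the planted-truth
tests therefore shows the algorithms are correct on data satisfying their
assumptions — it does not show robustness to the noise structure of real
resequencing or annotation pipelines.

## Problem sizes and numerical choices in the test suite

The suite runs at sizes chosen to exercise every code path while staying
comfortably interactive: exact-recovery assertions use the zero-noise
bundle (no random homolog hits — with 60-gene chromosomes and max gaps 25,
random anchors can legitimately chain, which is noise the exact-count
assertions must exclude); calibration uses 18 target + 300 background
promoters of 500 bp against 20 width-8 motifs, 200 null replicates (the
q ≤ 0.1 false-flag fraction stays below 0.1 + 2·SE) and 100 planted
replicates (detection in ≥ 95); the Pearson type-I check runs 10,000 null
replicates at n = 10; oracle-equivalence checks run 500 chaining
instances, 1,000 consequence substitutions, and 1,000 PROSITE peptides.

Other numerical conventions: NJ branch lengths clamped at zero; BH via
`stats::p.adjust` behind `bh_adjust()` (verified against the hand
step-up); enrichment p-values of exactly collinear expression vectors
reported as 0; suffix and reference ties flagged; deterministic
lexicographic tie-breaks throughout.

## Known limitations

- The enrichment z-test treats promoters as independent and the log
  affinity as normal; long shared repeats or strongly clustered families
  would violate both.
- `tree_clusters()` is a heuristic cut, not clade inference; on
  non-additive distances the two deepest splits need not be the two
  biologically meaningful clusters.
- Consequence annotation handles single-base substitutions exactly;
  multi-base substitutions within one codon are typed but not given a
  protein change.
- The collinearity score ties are resolved deterministically but other
  implementations may emit a different (equally maximal) chain when
  scores tie.
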