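---
title: "chipsmith: methods and design notes"
author: "chipsmith maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipsmith: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chipsmith re-implements, as a reusable and fully testable toolkit, the kind
of design pipeline behind genic SNP genotyping arrays for inbreeding crop
species — the pigeonpea 62K genic chip is the motivating case — together
with the analyses such arrays feed: genotype QC, diversity trees, gene
haplotype networks and segregation-distortion filtering for recombinant
inbred line (RIL) mapping populations. This vignette records the models,
conventions and open design choices; the README shows a worked example.

## Gene categorisation

Chip genes are drawn from five categories. Two are similarity-defined:

* **Single-copy test.** A gene is single copy when, searched against the
  full gene set, it matches only itself or its best *non-self* hit scores a
  bitscore below 200. We deliberately inspect the best non-self hit rather
  than only the rank-2 hit: the two coincide after the deterministic sort
  (bitscore descending, subject id ascending), and the best-non-self
  formulation is robust to ties and truncated hit lists.
* **Cross-species split.** Single-copy genes with no significant hit
  against the three reference legumes (chickpea, soybean, barrel medic) are
  SCP (lineage-specific single copy); those with a significant soybean hit
  are CSCSP (conserved single copy). "Significant" is an explicit bitscore
  cutoff, default 100, mirroring the curated-gene cutoff, because the
  original search parameters are not published in a reproducible form.
  Genes whose only significant cross-species hits are to chickpea or
  medic fit neither definition and are left UNCLASSIFIED rather than being
  forced into a class.

AGCP membership (homologs of cloned agronomic genes) uses curated-query
hits at bitscore ≥ 100, boundary included. DRDRP (disease
resistance/defense response) and MCP (multi-copy control) memberships are
curated id lists. When lists overlap, precedence is AGCP > DRDRP > MCP >
single-copy classes, and overlaps are reported rather than silently
resolved. The result is always a partition of the input gene set.

## Reference catalog

Each gene is extracted in full length plus 500 bp upstream and 100 bp
downstream of the translation start/stop (to capture proximal regulatory
sequence), reverse-complemented for minus-strand genes so catalog
coordinates always run 5′→3′ along the gene. Flanks that run off a contig
are truncated and the lost length recorded per flank. Coordinates are
1-based inclusive throughout (GFF3 convention), and
`extractedToGenomic()` inverts the mapping exactly — the test suite checks
the extraction/lift-back round trip on exon sequences of both strands.

## SNP catalog

Candidate sites arrive as per-site pileup summaries (TSV or a minimal VCF
with `DP`/`AR`/`ABQ`/`AF` INFO fields). A site passes when simultaneously
depth ≥ 10, alt-supporting reads ≥ 2, average base quality ≥ 25 and alt
allele fraction ≥ 0.05 — the published caller thresholds, all inclusive.
The caller itself is out of scope: the filter settings, not the caller,
are the method. Non-biallelic records are rejected with reason
`multiallelic`; every site gets a logged pass/fail reason.

Feature annotation is purely geometric in extracted coordinates: 5′ of the
first exon (including the added flank) is `five_prime`, within an exon
`exon`, between exons `intron`, 3′ of the last exon `three_prime`. The
source annotations do not distinguish annotated UTRs from the added
flanks, so neither do we; the convention is documented and the four
classes always partition the SNPs.

Category summaries derive density per kbp, mean gene size, SNPs per gene,
chip shares and inclusion rates from raw counts. Reported decimals use
round-half-up (`roundHalfUp()`); the acceptance checks use only derived
values that are stable under reasonable rounding conventions. One
published-table subtlety worth recording: the "percentage of genes in the
chip" column of the usual summary table is the category's share of chip
genes, while the prose "inclusion" percentages are chip genes over
reference genes per category. `summarizeCategories()` computes both under
distinct names.

## Probe design

Axiom-style assay geometry: a 72-bp plex with the target SNP at base 36
(35 bases 5′, 36 bases 3′, alleles in `[A/G]` bracket notation). Two
filters precede scoring:

* **Interference.** A target SNP is disqualified if another SNP lies
  within 10 bp on either side. We read "within 10 bp" as positional
  distance ≤ 10 (so neighbours 10 apart remove each other, 11 apart do
  not), and each SNP is evaluated independently, which makes the rule
  symmetric: both members of a close pair fail.
* **Plex geometry.** SNPs closer than 35/36 bases to the ends of the
  extracted sequence cannot fill the window and are marked
  `not_possible`.

The commercial per-probe conversion model is proprietary, so candidates
carry a *surrogate designability score*: a deterministic value in [0, 1]
starting at 1 with multiplicative 0.5 penalties for (i) flank GC fraction
outside [0.30, 0.70], (ii) a homopolymer run of ≥ 6, (iii) any flank
16-mer occurring more than once across the catalog (a cross-hybridisation
proxy), and (iv) ambiguity characters in the flanks. The decision gate is
the same as in production use: strictly greater than 0.50 is
`recommended`. The score's components and weights are documented
constants, configurable, and make no claim to reproduce any vendor's
numbers — only to preserve the pipeline's shape and its attrition
behaviour. One forward/reverse record is emitted per SNP; multi-probe
tiling schemes are out of scope. `designPipeline()` records survivor
counts at every stage so attrition is auditable, and the counts are
non-increasing by construction.

## Genotype QC

Calls are coded 0/1/2/−1 for AA/AB/BB/NoCall. Call rate (per sample or
SNP, with a 0.955 gate exposed on both axes), heterozygosity (AB over
non-missing), duplicate concordance (agreement over jointly called SNPs)
and minor allele frequency (allele counting) are standard. Intensity-space
sample QC (DQC) needs raw signal data and is out of scope; sample QC here
is call-rate based.

The RIL marker filter keeps markers homozygous and polymorphic between
the two parents, treats residual heterozygous line calls as missing
(appropriate for F8 inbreds), and applies the two-class chi-square
goodness-of-fit against 1:1, `(n_AA − n_BB)² / (n_AA + n_BB)` with one
degree of freedom and no continuity correction (standard linkage
practice); a marker is kept iff p ≥ 0.05. Under simulated fair
segregation with 94 lines the realized rejection rate is close to the
nominal 5% (the test discreteness at this sample size keeps it marginally
below), and planted 3:1 distortion is rejected essentially always — both
are recomputed by the acceptance script.

## Diversity and population structure

Distances are identity-by-state: one minus the mean shared-allele
proportion over jointly called SNPs (homozygote vs heterozygote shares
0.5). Trees use classic Saitou–Nei neighbor joining with deterministic
tie-breaking (lowest index pair in the Q matrix), implemented in-package
so the agglomeration order is a pure function of the input; the test
suite checks exact recovery of random additive trees (topology and path
lengths) and topological agreement with an independent NJ implementation.
The tree-building tool used in the original analyses advertises an
"improved" NJ variant whose details are unpublished; our claim is
cluster-level agreement, not branch-length equivalence to that tool.

The unlinked-subset rule — three SNPs per chromosome with MAF ≥ 0.30,
"near the telomeres and the centromere" — is operationalised as the
qualifying candidate nearest each of three anchor points: the two ends
and the midpoint of the chromosome's covered interval. With 11
chromosomes and dense candidates this yields exactly 33 SNPs; chromosomes
without qualifying candidates contribute fewer, with a warning. STRUCTURE
main-input export (two rows per individual, −9 missing) and PLINK
ped/map round-trip I/O are provided; running STRUCTURE itself is out of
scope.

## Gene haplotypes

Haplotypes are the concatenated homozygous alleles over all of a gene's
chip SNPs. The default `exclude` policy assigns only samples fully called
and homozygous at the gene — the chip-haplotyping convention for selfing
species, where analysed genes are chosen for complete call rates. A
`het_as_missing` policy recodes heterozygotes to `N` first and tolerates
a configurable missing fraction. The "sliding window" phrasing attached
to haplotype generation in some original workflows is ambiguous; defining
haplotypes over all of a gene's SNPs matches how SNPs per gene are
counted in the summary tables and is the convention here.

Diversity is Nei's unbiased estimator `Hd = n/(n−1) · (1 − Σ pᵢ²)`,
undefined for n < 2.

**Median-joining networks** (tolerance ε fixed at 0, the sparse
deterministic setting): iterate (a) build the minimum-spanning network —
the union of all minimum spanning trees, via Kruskal over ascending
weight classes admitting every edge of a class that links components as
they stood when the class opened — and (b) for every connected triple,
add the per-site majority-consensus median if it is new and strictly
reduces the triple's spanning cost; finally prune medians left with
degree ≤ 1. Ties in the consensus (all three states distinct) resolve
toward the triple's first node, and triples are enumerated in sorted
order, so the construction is deterministic under a fixed input ordering.
Guaranteed properties, all asserted in the tests: the network is
connected; edge weights equal the Hamming distances of their endpoints;
medians only add nodes; the network contains a minimum spanning tree over
its final node set; and any two observed haplotypes are connected using
only edges no heavier than their direct Hamming distance (the MST
minimax property). Note that the *sum* of weights along a network path
may exceed the direct Hamming distance — a direct edge is omitted
whenever its endpoints are already connected through lighter edges — so
path-length equality is not claimed.

**Subset saturation** draws seeded random SNP subsets of given sizes and
counts the haplotypes each resolves. The analysis is restricted to the
samples assignable on the full SNP set, so every subset partition is a
coarsening of the full partition: subset counts can never exceed the
full-set count, and the full-size subset reproduces it exactly. Without
that restriction the monotone bound would be false, because a smaller
subset can make additional (elsewhere-missing) samples assignable.

## Synthetic fixtures

The generators produce every input the pipeline consumes, seeded and
byte-for-byte reproducible:

* **Genome/catalog:** one padded contig per gene with planted multi-exon
  models; per-category mean gene sizes default to the published reference
  set (≈1.2–3.3 kbp).
* **Variant sites:** Poisson placement at per-category densities
  defaulting to the published values (SCP 35.2, CSCSP 6.9, AGCP 22.7,
  DRDRP 16.6, MCP 111.8 SNPs/kbp), with pileup fields drawn so
  configurable fractions (default 5% each) fail each site filter.
* **Population panel:** 95 samples in two subpopulations (56/39, with 18
  and 16 admixed individuals), Balding–Nichols allele-frequency
  divergence at Fst = 0.2 — a deliberately well-differentiated setting
  chosen so subpopulation recovery is a property of the method, not of a
  marginal simulation — 9.79% mean heterozygosity and 0.73% no-calls,
  matching the validation panel statistics the design is known for.
  Genotypes are drawn homozygous-by-default with an explicit heterozygote
  probability, as appropriate for a predominantly selfing species; a
  binomial Hardy–Weinberg draw would give several-fold higher
  heterozygosity than such panels show.
* **RIL matrix:** 94 lines plus two fixed opposite-homozygous parents,
  residual heterozygosity (1/2)^(F−1) per locus (F8 default: 0.0078),
  independent markers (linkage-map construction is out of scope), and an
  optional planted fraction of 3:1-distorted markers.

What the fixtures do *not* emulate: linkage disequilibrium and
recombination maps, coalescent genealogies, raw intensity data, indels,
and sequencing error structure. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical structure, not
performance on any particular real data set.

## Numerical choices and problem sizes

Rounding of reported statistics is half-up at the printed precision.
All RNG flows through explicit seed arguments; sub-streams are derived
arithmetically from the one seed. Degenerate inputs are defined, not
accidental: empty categories summarise to zeros, monomorphic SNPs have
MAF 0, samples with no calls have NA heterozygosity, and zero-overlap
sample pairs are an error naming the pair. The test and acceptance runs
use deliberately desk-scale sizes — 1,000-SNP panels, 1,000-marker RIL
matrices, trees to 8 taxa, networks to ~8 observed haplotypes — chosen so
the whole suite re-runs in well under an hour on one core while keeping
Monte-Carlo error far inside the asserted tolerances.

## Known limitations

Published chip-content counts (total SNPs discovered, genes and SNPs on
the final array, per-gene haplotype counts of specific genes) depend on
unreleased sequence and genotype data and are not reproducible from this
package; they enter only as printed count columns whose *derived*
statistics the summary arithmetic reproduces. The surrogate designability
score shares only the gate and the shape of the real conversion model.
The unlinked-subset anchors are a documented proxy for unavailable
telomere/centromere coordinates.
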