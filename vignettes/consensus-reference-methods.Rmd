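---
title: "Building and evaluating a population consensus reference"
author: "consensusRef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating a population consensus reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusRef)
```

# The problem

A reference genome assembled from one donor encodes that donor's alleles.
Aligning any other individual against it produces a large background of
"variants" that are nothing but sites where the donor happens to carry a
minor allele: they surface predominantly as homozygous calls shared by most
of the population. A *consensus* (variome) reference replaces the donor's
bases with the alleles most common in a sequencing cohort, so that
downstream call sets shrink to what is actually individual.

`consensusRef` implements the construction of such a consensus from a
baseline reference plus a cohort VCF, the coordinate bookkeeping it induces
(lift-over chains), and the comparison machinery used to quantify the
effect — plus the structural-variant concordance, assembly-statistics and
chromosome-building tools that accompany a reference-building project.

# The consensus model

## Haploid tallies under a ploidy scheme

All counting is over *called haploids*. A `PloidyScheme` assigns each
sample a per-chromosome ploidy: 2 on autosomes; on X, 2 for females and 0
for males (only female genomes inform X); on Y, 1 for males and 0 for
females. For the default 40-sample cohort of 25 males and 15 females this
gives capacities 80/30/25 for autosomes/X/Y. Missing genotype slots are
excluded from allele counts and from the called-haploid denominator but
never from the chromosome *capacity*; genotype arity inconsistent with the
scheme (a diploid call on Y) is an error, not a reinterpretation.

`tallyAlleles()` decomposes every VCF record per alternate allele,
normalizes each ref/alt pair (shared suffix then prefix trimmed; pure
indels left-aligned through repeat context when the reference is supplied)
and keys sites by the normalized `(chrom, pos, ref-span)`. The reference
count at a site is the called haploids not carrying any of that site's
alternates — so at a multiallelic site the alleles compete against each
other *and* the reference. Identical normalized events from different
records aggregate by summing supporting counts and called denominators;
cohort callers emit one record per site, so this path is a safety net, not
a common case.

## Substitution rules

* **SNVs** (`selectSnvSubstitutions`): substitute the site's most frequent
  single-base allele, only when it differs from the reference base. A tie
  has no unique most-frequent allele, so ties keep the reference — the
  conservative reading of "substitute the most frequent allele *if it
  differs*". The comparison uses called haploids only; missingness shrinks
  the denominator.
* **Indels** (`selectIndelSubstitutions`): substitute when supporting
  haploids strictly exceed `indelFraction` (default 0.5) of the
  chromosome's haploid *capacity* — the absolute-count reading of a
  "more than 40 of 80 haploids" threshold: 40/80 fails, 41/80 passes,
  16/30 passes on X. Using capacity, not called haploids, keeps the
  threshold absolute; a heavily missing site cannot sneak in with fewer
  carriers.
* **Conflicts** (`combineEditCandidates`): SNVs are accepted first; indels
  follow in decreasing support order and are dropped (and reported) when
  their reference span overlaps any accepted edit. The order is a design
  choice — no canonical rule exists — and a deterministic precedence keeps
  the edit script valid and the report auditable. Every candidate appears
  in the edit report with its haploid support and accepted/dropped status.

Pseudo-autosomal regions receive no special treatment (whole-X female,
whole-Y male counting); `ploidyScheme(overrides=)` accepts per-chromosome
ploidy overrides where a cohort needs them.

## Edit application and the induced chain

`applyEdits()` replaces each edit's reference span left to right.
Length-preserving substitutions do not interrupt alignment blocks; each
indel closes the current block and opens a source gap (deleted bases)
and/or target gap (inserted bases). The result is a forward-strand,
same-chromosome `Chain` whose blocks are strictly increasing in both
coordinate systems — the in-memory form of a UCSC lift-over file, written
and re-read bit-exactly by `writeChain()`/`readChain()`.

Conventions worth noting:

* Coordinates are 0-based half-open everywhere inside the package;
  conversions happen only at format boundaries (VCF and AGP are 1-based).
* Edits are left-aligned, so an insertion is anchored at the leftmost
  equivalent position; the first unedited base after an insertion point
  maps to the coordinate following the inserted run in the target.
* A variant span partially overlapping a block edge lifts as `UNMAPPED`
  rather than truncated — truncation would silently change alleles.
* `liftCalls()` re-reads the reference allele from the target sequence.
  When it differs (the consensus absorbed a substitution), the status is
  `REF_CHANGED` and alleles plus genotype are re-expressed against the new
  base: a genotype homozygous for the absorbed allele becomes
  homozygous-reference — the variant vanishes, which is precisely the
  consensus effect being measured.

# Comparison semantics

`restrictToSharedRegions()` keeps calls whose spans are mappable under
every supplied chain, so cross-reference counts are made over the mutually
alignable genome. The default mode requires the whole variant span inside
one aligned block; a per-base mode (`mode = "base"`) is available since
the span-vs-base choice is a genuine ambiguity — the difference only
touches variants straddling insertion points.

`referenceSpecificVariants()` matches variants after lift-over by
normalized position, alleles *and* genotype-carried alleles, so
representation drift cannot inflate reference-specific counts.
`REF_CHANGED` lifts that re-express to homozygous-reference are counted as
A-specific absences, not matches. `sharednessSpectrum()` tabulates, over
the union of observed variants, in how many individuals each occurs.

# SV concordance and the S/P filter

Two deletions/inversions are the same event when types match and the
intersection covers at least 50% of *each* record (inclusive boundary —
an exactly-50% pair matches). Insertions have no reference extent, so the
package uses breakpoint proximity (default window 1 kb) plus a reciprocal
length ratio ≥ 0.5; this is a documented surrogate, not a rule the
span-overlap criterion defines. `clusterSharedSVs()` single-links the
pooled records under this identity and assigns every cluster to the exact
label set it contains; single linkage is the weakest assumption that
yields a partition, and the decomposition is invariant to input order.

The S/P filter compares a region's single-end/properly-paired read counts
with the genome-wide counts by a two-sided Fisher's exact test
(`stats::fisher.test` behind `fisherExact()`; the test suite checks it
against an exhaustive fixed-margin enumeration) and discards only regions
that are significant at α = 0.001 *and* inflated — misassembly attracts
wrongly mapped single-end reads, so the deflated direction is never
evidence against an SV. A region with zero paired reads counts as
maximally inflated. Group enrichment uses the same test at α = 0.05 with
the direction requirement on the in-group frequency. Whether the original
test was one- or two-sided is not documented anywhere we could verify;
two-sided with a directional post-condition is the conservative
combination.

# Assembly statistics and chromosome building

`nxxLxx()` uses the cumulative-sum definition: Nxx is the largest length
L such that fragments ≥ L sum to at least x% of the total included
length, Lxx the count of such fragments; the denominator is the total of
fragments passing `minLen` (the "total ≥ 200 bp" reporting convention),
with genome-size denominators available for gap fractions, since published
tables mix both. `novelRegions()` reports maximal runs with depth ≥ 3 and
length ≥ 100 (both inclusive; a 100 bp run qualifies, runs are never
merged across sub-threshold bases). The upstream filtering that produces
an unmapped-read set is out of scope; the module consumes a depth track.

`placeScaffolds()` applies three passes: primary (large scaffolds,
≥ 7 anchors on one chromosome), rescue (remaining large scaffolds, ≥ 4
anchors, optionally from a second alignment), and small scaffolds only
through mapping-quality-254 anchors. A scaffold tied between chromosomes
stays unplaced with a warning; otherwise the anchor-richest chromosome
wins — the tie/conflict rules are package decisions where no published
rule exists. Orientation is the majority anchor strand (ties: plus, with
a warning). Gaps between placed scaffolds are their reference distance
when positive and a fixed 10 kb when placements overlap *or abut* — AGP
gap rows need positive lengths, so zero-distance abutment joins the
overlap rule. Chromosomes get 10 kb telomeric N-pads; unplaced scaffolds
concatenate into `chrUn` with fixed 10 kb spacers (mirroring the pad
convention; no spacer rule is published). The emitted AGP 2.0 reproduces
the FASTA byte-for-byte via `agpToSequences()` — the format's defining
contract, property-tested on random fragmentations.

# The simulators, and what passing tests do and do not show

`simulateCohort()` emulates the *structure* of a real cohort — per-site
population frequencies with Hardy-Weinberg genotypes, sex-dependent
ploidy, missingness, VCF-style indel representation — at desk scale:
50 kb autosome, 2,000 SNV and 200 indel sites, 40 samples (25 M / 15 F),
2% missingness, plus small X/Y chromosomes so the 30/25-haploid arithmetic
is exercised. Site frequencies are uniform on (0, 1), which yields a rich
mix of major-allele and reference-major sites; indel carrier counts are
planted exactly (the threshold boundary pair, e.g. 40 and 41 of 80, is
always present) with no missingness at indel sites, so threshold behaviour
is deterministic. The truth table records the *realized* cohort-major
allele counted by the generator's own bookkeeping — exact parameter
recovery is only defined against realized counts, and the latent frequency
is recorded alongside. Planted indels are generated already left-aligned
and trim-stable, so normalization cannot relocate them away from their
truth keys.

What the generators do **not** emulate: linkage and haplotype structure,
repeat-induced representation ambiguity beyond simple runs, caller
artefacts (the genotypes are drawn, not called from reads), population
structure, and genome-scale site densities. Passing recovery tests
therefore demonstrates the correctness of the counting, thresholding,
splicing and mapping machinery — not robustness to real caller noise.
Likewise the homozygous-call reduction reproduced on held-out individuals
is the qualitative phenomenon; its magnitude on real data depends on real
allele-frequency spectra.

`simulateSVUniverse()` plants each SV cluster in its own 100 kb window
with jitter comfortably inside the reciprocal-50% identity, so recovered
sharing groups must equal the design exactly. `simulateSPCounts()` draws
region totals of at least 100 reads with single-end fractions at the
genome rate (authentic) or 10× it (spurious). `fragmentAssembly()` cuts a
chromosome into contiguous oriented fragments with exact quality-254
anchors. All generators are pure functions of their seed, restore the
caller's RNG state, and are byte-reproducible.

# Numerical and scale choices

Fisher p-values use exact hypergeometric arithmetic with the customary
1 + 1e-7 relative tolerance on the point-probability comparison; the test
suite requires agreement with an independent enumeration oracle to 1e-10.
The test and acceptance runs use problem sizes chosen to exercise every
rule while keeping a full run in the minutes range on one CPU: the
default 50 kb cohort for recovery and the 100-replicate reduction
property, 200 random edit scripts with 10,000 mapped positions each,
1,000 random length multisets, 100 seeded fragmentations of a 30 kb toy
chromosome. Degenerate inputs have defined behaviour throughout: empty
edit scripts yield identity chains, all-zero contingency tables return
p = 1 with a warning, empty fragment sets and empty known-SV lists are
errors or all-novel respectively, and zero-length gap rows cannot arise
by construction.

# Known limitations

* Consensus construction assumes substitution-only edits; chains never
  rearrange or change strand, and general whole-genome-alignment chain
  generation is out of scope.
* Indel left-alignment handles pure insertions/deletions; complex
  multi-nucleotide replacements are trimmed but not repositioned.
* The insertion identity criterion (window + length ratio) is an
  interpretation; analyses sensitive to it should vary `insWindow`.
* The X/Y scheme is whole-chromosome; fine-grained pseudo-autosomal
  handling requires explicit ploidy overrides.
* VCF parsing requires GT and supports up to diploid genotypes.
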