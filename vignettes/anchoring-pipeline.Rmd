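---
title: "Anchoring draft assemblies to genetic maps with AnchorMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring draft assemblies to genetic maps with AnchorMap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AnchorMap)
library(Biostrings)
```

## The problem

Long-read assemblies of plant genomes typically arrive as a few hundred
contigs. To turn them into chromosome-scale sequence one needs an external
source of long-range order: a genetic linkage map, whose markers have known
linkage groups and centimorgan (cM) positions, and whose probe sequences can
be located on the contigs. AnchorMap implements this anchoring procedure for
the common design in which an F1 cross provides two parental maps of unequal
density (here called the female and male maps), each marker being a 70-bp
array probe.

The pipeline has five stages, each exposed as its own function and run
end-to-end by `anchorAssembly()`:

1. **Probe placement** (`placeMarkers()`). Every probe is aligned to both
   strands of every contig by a seeded ungapped aligner (`alignProbes()`):
   exact k-mer seeds (default k = 11) nominate candidate placements, which
   are scored by full-length Hamming comparison. A marker is kept only if it
   has a *unique* best hit and that hit has at least 95% matches and at most
   4% mismatches, both fractions computed over the full probe length.
   Markers with tied best hits are eliminated as ambiguous before the
   identity thresholds are applied; a second-best hit a single point below
   the best does not eliminate.
2. **Linkage-group assignment** (`assignLinkageGroups()`). Each contig takes
   the modal linkage group of its placed markers; markers on that group are
   *concordant*, the rest discordant. Contigs need more than one concordant
   marker to be anchorable.
3. **Chimera detection and splitting** (`detectChimeras()`,
   `splitContigs()`). A contig whose markers form exactly two contiguous
   physical blocks (at least two markers each) from two linkage groups is an
   assembly artefact; it is cut at the midpoint between the flanking
   markers, producing `<name>_a` and `<name>_b`. Interleaved patterns (e.g.
   1,5,1,5) cannot be attributed to a single junction; such contigs are
   excluded as irresolvable rather than guessed at.
4. **Ordering, orientation, integration** (`orderContigs()`,
   `orientContigs()`, `integrateMaps()`). Within each linkage group contigs
   are ordered by the arithmetic mean cM of their concordant markers
   (ties: descending length, then name); orientation is the sign of the
   Spearman correlation between marker physical and genetic positions, `?`
   when undefined or when the two maps disagree. The female map (the denser
   one) takes priority in integration: male-only contigs are inserted
   between their male-map neighbours that are also female-anchored, and
   contigs whose two maps assign different linkage groups are excluded and
   reported. Everything unanchored goes to Chr0.
5. **Building** (`buildPseudomolecules()`). Contigs are concatenated with a
   fixed gap of 10,000 N between consecutive contigs; `-` contigs are
   reverse-complemented, `?` contigs written forward but recorded as `?` in
   the AGP v2.1 ledger. Chr0 is built the same way from the unanchored
   contigs in descending length order, and the unplaced contigs are also
   returned individually (the community convention); the concatenated Chr0
   object keeps whole-assembly totals comparable.

```{r pipeline}
sim <- simulateGenome(nChrom = 3, chromLength = 2e5, copies = 50, seed = 1)
cs  <- fragmentContigs(sim, nContigs = 20, chimeraCount = 2, seed = 1)
maps <- simulateMaps(sim, nFemale = 400, nMale = 160, seed = 1)
res <- anchorAssembly(contigSeqs(cs), maps$female, maps$male)
res$plan
as.data.frame(res$report$per_chromosome)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 11 | seed length (bases) of the probe aligner; placements with up to `floor(70/k) - 1` mismatches are guaranteed to be found |
| `minMatch` | 0.95 | minimum match fraction of a retained hit, over the full probe length |
| `maxMismatch` | 0.04 | maximum mismatch fraction; with 70-bp probes this admits at most 2 mismatches |
| `band` | 10 | score band (score = matches − mismatches) within which secondary hits are reported, so ambiguity can be detected |
| `minMarkers` | 2 | concordant markers required to anchor a contig |
| `gap` | 10000 | N-gap (bases) between consecutive contigs in a pseudo-molecule |

## The synthetic-data generator

Simulated data are the package's test bed, and every simulator output is
truth-tracked: `SimGenome` records the planted satellite arrays,
`ContigSet` records each contig's source segments (and hence each chimera's
true junction), and `simulateMaps()` returns each marker's true genome
position.

What it emulates: a multi-chromosome haploid genome (i.i.d. uniform
residues outside planted arrays); one centromeric satellite family with a
159-bp monomer planted as a single tandem array per chromosome with a few
percent substitution divergence; fragmentation into contigs including a
configurable number of two-chromosome chimeras with junctions at least 5 kb
from contig ends (so both sides can carry markers); two parental maps whose
cM coordinates are linear in the genome coordinate (default 4 cM/Mb) —
monotonicity is the only property the pipeline uses, so no interference
model is fitted; probes as exact 70-bp genome substrings, a configurable
fraction carrying a fixed number of substitutions to exercise the quality
filter; per-sample variant tables as a Bernoulli process with a
homozygous/heterozygous mix.

What it does not emulate: base composition and repeat landscape of real
plant genomes beyond the one satellite family, structural variation other
than two-segment chimeras, genotyping error in the maps themselves (map
positions are error-free), read errors other than substitutions, and
polyploid genotypes. Passing tests therefore demonstrate algorithmic
correctness against known truth, not robustness to every artefact of real
data.

A single global seed drives one named random stream per operation, so
adding a new operation never changes the fixtures produced by existing
ones.

## Auxiliary computations

**Tandem-repeat discovery** (`findTandemArrays()`): exact k-mers (default
k = 8) vote for candidate periods via the distance to their previous
occurrence; runs of same-period votes delimit candidate arrays, refined by
per-column majority consensus over the copies. Using *successive*
occurrences suppresses period harmonics, and overlapping candidates are
resolved greedily by vote count. Exact 8-mers tolerate the few percent of
divergence typical of satellite arrays. `clusterRepeatFamilies()` links
arrays whose consensus monomers are at least 80% identical under the best
cyclic rotation and strand (tandem monomers have no intrinsic phase), by
single linkage; `repeatDensityTrack()` computes windowed coverage of a
family and calls one candidate centromeric interval per chromosome as the
maximal run of windows at or above 50% coverage. This assembly-based
localization replaces read-mapping-based localization: the goal (a
repeat-dense interval per chromosome) is the same, but no external aligner
is involved.

**K-mer genome size** (`kmerGenomeSize()`): canonical 25-mers of the reads
are counted via exact 2-bit rolling hashes (4^25 < 2^53, so doubles are
exact); the coverage peak is the histogram mode at multiplicity ≥ 2
(multiplicity 1 is dominated by sequencing errors), genome size is total
k-mers divided by the peak, and k-mers within [peak/2, 1.5·peak] scale to
the unique-sequence portion. Two caveats follow directly from the argmax
rule: the estimate carries a bias of up to half a multiplicity unit in the
peak (about 1.3% at 20× read coverage — within the 2% tolerance the tests
assert), and a genome with *no* single-copy sequence has no single-copy
peak at all, so the estimator degenerates to the repeat-unit size; the
repetitive-fraction test fixture therefore includes a small unique portion
alongside a dominant repeat.

**Variant summaries**: `windowDensity()` counts variants in fixed-origin
200-kb windows, normalizing the final partial window by its true span to
avoid edge inflation; `hetSummary()` reports per-sample hom/het fractions;
`homSnpAlignment()` merges homozygous SNPs across samples into a
variable-sites-only matrix for phylogenetic input — a sample contributes
its homozygous allele, the reference allele where it has no call, and `N`
where its own call is heterozygous (excluded as missing data rather than
assumed reference). `colinearityStats()` validates a build against an
independent map by per-linkage-group Spearman correlation and lists
relocation candidates (contigs, including Chr0 contigs with at least two
markers of one group, whose independent-map markers vote for a different
chromosome).

## Numerical and design choices

- Coordinates are 1-based closed intervals throughout (the
  IRanges/Biostrings convention); AGP and VCF are 1-based by definition, so
  conversion happens nowhere.
- `N` never matches anything in alignment scoring, including another `N`.
- Marker elimination order follows the two-stage funnel: ambiguous
  (tied-best-hit) markers are removed before the identity thresholds are
  applied, so the reported rejection reasons partition the markers
  unambiguously.
- The chimera cut point is the midpoint of the inter-block marker gap — the
  breakpoint is only localized to that interval, and the midpoint is the
  symmetric, deterministic choice.
- Modal-linkage-group ties are never silently resolved: two-block patterns
  go to chimera detection, everything else is excluded as irresolvable.
- Orientation falls back to `?` (written forward, recorded faithfully in
  the AGP) rather than borrowing order from a related genome's synteny;
  external-genome evidence is out of scope.
- Satellite consensus is the per-column majority over copies; copy number
  is the array span divided by the period, so it is a real number and
  detection asserts it only to ±1.

## Problem sizes

The test suite and the acceptance script run on scaled-down genomes
(hundreds of kb per chromosome, 100–600 markers per map, 15–20× read
coverage), sizes at which every algorithm's behaviour — including the
brute-force oracles the tests compare against — can be verified exhaustively.
All stages are linear or near-linear in genome length and marker count, and
the same code paths apply unchanged at real-genome scale.

## Known limitations

- The aligner is ungapped: a probe spanning an indel in the assembly is
  rejected by the identity filter instead of being gap-aligned. For
  same-genotype assemblies this loses almost nothing.
- Only one split per contig is supported (a three-way chimera would be
  flagged irresolvable).
- Tandem arrays with periods outside [2, 2000] or fewer than `minCopies`
  copies are not reported; nested or higher-order repeat structure is
  collapsed into the fundamental period.
- The k-mer estimator assumes error-free or low-error reads at ≥10×
  coverage; an error spike at multiplicity 1 is tolerated but not modelled.
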