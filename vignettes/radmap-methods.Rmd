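---
title: "Methods: pseudo-testcross mapping, anchoring and recombination landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-testcross mapping, anchoring and recombination landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`radmap` re-implements, as a tested pipeline, the computational chain
used to turn RAD-seq genotypes of an F1 outcross family into a
chromosome-level view of a scaffold assembly: marker calling, linkage
mapping, scaffold anchoring, and a Marey-map recombination landscape.
Everything runs on a seeded synthetic world with complete ground
truth; nothing requires external data.

### Pseudo-testcross design

Both parents of an F1 family of an outcrossing species are highly
heterozygous.  A site where the seed parent is heterozygous (alleles
X/Y) and the pollen parent homozygous (XX) behaves like a testcross
for the maternal meiosis: progeny are XX or XY with probability 1/2
and the maternal map can be built from them alone.  `define_markers()`
encodes exactly this rule: seed parent showing exactly two alleles
(each with depth ≥ `min_parent_depth`, minor fraction ≥
`het_min_minor_frac`), pollen parent showing exactly one allele which
must be one of the seed parent's two.  Only the maternal map is built;
the paternal map would use the mirrored rule and is out of scope.

`call_genotypes()` calls 1 (heterozygote) on any read of the
Y allele, 0 otherwise, and requires a total site depth of at least 3
reads (`min_depth`); whether the threshold applies to the site total
or per supporting allele is not derivable from the source pipeline's
internals, so the site-total interpretation is the default and a
per-allele mode is exposed (`mode = "allele"`).

### Two-point linkage

Linkage phase is unknown in an outcross.  For markers *i*, *j* with
*n* co-called progeny and *M* mismatching calls, the phase-folded
estimate is `r = min(M, n-M)/n` (coupling if mismatches are the
minority).  The two-point LOD against free recombination is

    LOD = R log10(2r) + (n - R) log10(2(1 - r)),   R = min(M, n - M),

with `r` clamped to `[1/(2n), 1/2]` purely so that co-segregating
pairs (R = 0) stay finite; map distances are computed from the
*unclamped* estimate so that co-segregating markers sit at one
position.  Groups are single-linkage connected components of the
`rf < 0.4 & LOD > 10` graph — the standard strict criteria for
validating outcross RAD groups.  With the default scaled world
(~27 cM chromosomes, 184 progeny) these thresholds cleanly separate
chromosomes; a real chromosome with a > 30 cM marker desert would
split into two groups, which is expected behaviour for this class of
data (the motivating study had three chromosomes resolved into two
linkage groups each).

### Ordering

Maximum-likelihood ordering in the original toolchain is proprietary;
`order_markers()` replaces it with an explicit, documented heuristic:

1. Markers that co-segregate perfectly (`min(M, n-M) = 0` over ≥ 20
   co-called progeny) are binned; they are unresolvable at the family
   size and are re-expanded at a single map position.
2. An end bin is identified as the bin maximising the summed Haldane
   distance to all others (summing averages away the noise of
   individual estimates), and bins are seeded in order of distance
   from it.
3. The order is refined to a local optimum of the SARF criterion (sum
   of adjacent Haldane distances) under 2-opt (segment reversal),
   Or-opt (relocation of segments of length ≤ 3) and exhaustive
   permutation of a sliding window of five bins.  The compound
   neighbourhood matters: plain 2-opt stalls on folded paths it can
   only unfold through worse intermediate states.
4. Orders are canonicalised (first marker id < last marker id), since
   an order and its reversal are the same map.

Two-point data has a known residual ambiguity: a double crossover in
one progeny can make two adjacent bin orders equally parsimonious
(identical obligate recombination counts, likelihood ties).  When a
scaffold spans both bins, its internal physical order resolves the tie
— the standard use of assembly information in a genome project — and
`order_markers()` applies exactly that tie-break, only when the SARF
difference between the two orders is below `tie_eps` (default
0.15 cM, i.e. well under one recombination event at n = 184, 1/184 →
0.54 cM) and only in the direction supported by the scaffold's
orientation as estimated from its markers *outside* the tied pair.
Ties between bins not sharing a scaffold remain unresolvable and are
left as the data orders them; on the default world this affects at
most a pair of markers in an occasional seed.

Map positions are prefix sums of adjacent-pair Haldane distances,
`d = -50 ln(1 - 2r)` cM — exact for crossovers without interference,
which is also precisely the simulator's meiosis model, so map-length
recovery is a calibrated end-to-end check rather than a tautology.

### Anchoring

Scaffold → group assignment is by marker majority; a scaffold with at
least two markers on each of two groups is flagged as a putative
chimera and left unplaced (the threshold of two guards against a
single mis-mapped marker).  Scaffolds are ordered by the mean cM of
their supporting markers (the alternative — flanking-marker intervals
— is not recoverable from the source and mean-cM is logged as the
package's choice), oriented by the sign of the Kendall correlation
between within-scaffold bp and cM (needing ≥ 2 distinct values of
each; `?` otherwise), and concatenated into pseudomolecules named
`Chr1..ChrK` by decreasing length with 100 bp `U` gaps ("contig",
linkage evidence "map") — the gap convention is the package's own, as
the source states none.  Single-marker scaffolds are placed at their
marker's position with unknown orientation by default
(`place_single_marker = FALSE` leaves them unplaced).

### Recombination landscape

The Marey map pairs each anchored marker's pseudomolecule coordinate
with its map position.  Per chromosome the cM track is flipped if it
runs against physical coordinates, then repaired to monotone by the
longest non-decreasing subsequence (ties kept; the source does not
state its treatment of discordant markers).  Rates are computed on
inter-marker intervals, not fixed windows: only interval rates can
reach the extreme values a hotspot produces over a few tens of kb
(window averaging would dilute them).  The genome average is
length-weighted (`Σ ΔcM / Σ ΔMb`) — the mean of interval rates would
up-weight short intervals.  Hotspots are merged runs of intervals with
rate strictly above `fold × average` (default 10); the merged rate is
recomputed over the merged span, so reported hotspot counts depend on
the merge convention (documented, switchable with `merge = FALSE`).
Coldspots are maximal zero-ΔcM runs spanning more than 1 Mb.  Gene
membership of a region is by gene start (unambiguous counting); gene
density is genes per 100 kb.

## The synthetic world

The generator's defaults are the package's stated test conditions, not
tuning knobs:

| parameter | default | rationale |
|---|---|---|
| chromosomes | 19 × 5 Mb | the target karyotype, scaled ~10× down so the pipeline runs in minutes on one CPU |
| progeny | 184 | the mapping family size of the motivating study |
| marker density | 30 /Mb | RAD-like density; ~0.2 cM spacing at the default background |
| background rate | 5.5 cM/Mb | the genome-wide average of the motivating study |
| hotspots | 3 × 100 kb at 100 cM/Mb | > 10× background, mid-arm on the first three chromosomes |
| coldspot | 1 × 2 Mb | above the 1 Mb calling span, on the fourth chromosome |
| gene density | 2.82 /100 kb, ≥ 3-fold sinusoidal variation | the study's genome average; variation so density association is testable |
| mean gene length | 11 538 bp | the study's mean gene length |
| GC | 34.4% | the study's genomic GC, used for sequence emission |
| genotyping error e | 0.5% | not reported by the study; a typical RAD figure, config-exposed |
| missingness m | 15% | not reported; typical for RAD genotype matrices, config-exposed |
| depth | Poisson(8) progeny, Poisson(30) parents | parents sequenced ~2.5× deeper, as in RAD practice |

Meioses draw a Poisson number of crossovers per chromosome (mean = map
length in Morgans) with positions proportional to the planted
intensity — no interference, hence exactly Haldane-consistent.  The Y
allele's linkage phase is randomised per marker so phase inference is
actually exercised.  Pileup depths are Poisson and *consistent with
the (error/missingness-affected) calls*: a heterozygote with depth ≥ 2
always shows both alleles, an erroneous call is represented by reads
supporting the erroneous genotype, and a missing call by zero reads.
What the generator does **not** emulate: read-level sequences,
restriction-site dropout structure, depth correlation between
neighbouring sites, segregation distortion, and genotyping error that
correlates with depth.  A green recovery test therefore establishes
correctness of the mapping chain under its own model assumptions, not
robustness to every real-data pathology.

## Numerical and design choices

- Coordinates are 0-based half-open internally; GFF3 and AGP are
  emitted 1-based inclusive.  Orientation vocabulary is `{+, -, ?}`.
- Printed-statistic helpers round half-away-from-zero (base R rounds
  half-even), matching how the reproduced figures were printed.
- `rf` is clamped at `1/(2n)` only inside the LOD; distances use the
  raw estimate.
- Duplicate-individual removal (identity ≥ 0.95 over ≥ 100 shared
  markers, keep the less-missing member) uses thresholds chosen by
  this package: the source states the step but no values.  At the
  default 19-chromosome scale, independent sibs have identity
  ≈ 0.5 ± 0.1, so 0.95 is ~4.5 sd away; on very small toy genomes
  (few chromosomes) sib identity variance is large and the filter
  *will* flag true sibs — use `dup_identity` closer to 1 there.
- The seed of every generator is explicit; one master seed derives
  per-stage child seeds, and identical seeds give byte-identical
  outputs (tested).
- Chromosome naming is by decreasing pseudomolecule length; linkage
  group → karyotype chromosome assignment is external evidence (FISH
  in the motivating study) and only supported as a renaming table.

## Known limitations

- Ordering is two-point only; no multipoint/HMM likelihood, no
  interference model (Kosambi), no sex-averaged map.
- Two-point likelihood ties (double crossovers) that do not fall
  within one scaffold stay unresolved; Kendall τ against truth can be
  ~0.005 below 1 for an affected group.
- Map length is biased slightly upward at finite family size (Haldane
  is convex in `r`); at n = 184 and ~27 cM chromosomes the bias is
  well inside the 3-SE recovery band used by the tests.
- Missing genotype data degrades dense two-point maps more than it
  degrades grouping or anchoring: a bin distinction carried by a
  single recombinant progeny disappears whenever that call is missing,
  so co-segregation bins over-merge, ordering noise grows, and the
  summed map length inflates (tens of percent at m = 15% with
  0.2 cM marker spacing).  Real RAD maps behave the same way — map
  lengths from such data are conventionally reported as lower bounds
  ("at least ... cM").  The recovery guarantees tested here are for
  complete data; with missing data, grouping, scaffold assignment and
  hotspot positions remain reliable while absolute cM totals should
  be read as upper estimates.
- Hotspot *counts* depend on the interval/merge convention; published
  counts at full scale are context, not a target (see
  `reference_summary()`).
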