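---
title: "Detecting and dating conserved noncoding elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating conserved noncoding elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Conserved noncoding elements (CNEs) are noncoding genomic segments retained
at high sequence identity across distantly related species — here, at least
100 bp at >= 70% identity — many of which act as developmental enhancers.
`cnevol` implements a complete desk-scale pipeline for studying their
evolution across a fish-like cohort: de novo detection from pairwise
whole-genome alignments in two focal species pairs, a cross-genome
presence/absence search, reconstruction of the repertoire present in the
common ancestor of the two most basally splitting clades, dating of each
element's origin against outgroups (vertebrate-wide, Neopterygian — shared
with a gar-like outgroup — or post-3R-duplication teleost-specific),
genomic-zone profiling, synteny-based gene-target association with a
bootstrap resampling null, whole-genome-duplication (WGD) paralogy
clustering, CNE-based phylogenomics, and consensus-motif scanning.

Because multi-gigabase genomes are out of reach on a desk, every stage is
validated on a bundled genome-evolution simulator with complete ground
truth. This vignette records the models, the tunable parameters, and the
design decisions taken where the design was genuinely open.

## The detection model

Detection runs per focal pair on netted pairwise alignments:

1. **Alignment.** The internal aligner finds exact seed matches
   (`seed_length = 12`, seeds containing `N` are never formed) on both
   strands and extends them without gaps under an x-drop rule
   (`x_drop = 15`), scoring match `+1`, mismatch `-2`; blocks are trimmed
   back to their maximum-scoring extent and discarded below
   `min_block_score = 30`. Two rounds are run, with all round-1 footprints
   hard-masked before round 2, so homologies shadowed by a stronger copy
   get a second chance. The aligner is deliberately simple because the
   simulated cohorts are substitution-only (true alignments are exact
   position maps); alignments of real genomes are expected to be imported
   from an external aligner via the AXT reader, with the external
   parameterisation carried opaquely in `aligner_params$external_params`.
2. **Chaining.** Blocks are joined into maximum-score collinear chains by
   dynamic programming per (reference sequence, query sequence, strand)
   group. A link costs `gap_open_cost + per_bp_gap_cost * (ref_gap +
   query_gap)` with defaults 50 and 0.5, links are forbidden beyond
   `max_gap = 10,000` bp on either side, and the best chain is extracted
   repeatedly so each block belongs to exactly one chain. These chaining
   costs are this package's own defaults (stated so runs are reproducible)
   and are config-exposed.
3. **Netting.** Chains are kept greedily by descending total score on
   reference intervals not yet covered, trimming at base granularity; net
   coverage is asserted overlap-free on every output. Ties break by lower
   reference start, then lower query start — the tie rule used everywhere
   in the package.
4. **Window scan.** Alignment columns whose reference base overlaps an exon
   or repeat are excluded; a 100-column window slides one column at a time
   over excluded-free stretches and marks all its columns when at least
   70% match. Two open choices are fixed here: *gap columns count as
   mismatches*, and *no window spans an excluded column* (the stricter,
   simpler readings; both are config-switchable through `detect_params`).
5. **Merging and boundary refinement.** Maximal runs of marked reference
   positions become candidate elements. Because a qualifying window can
   straddle an element's true edge, a raw run may carry a flank stretch
   whose local identity is far below threshold; each run is therefore
   refined to its maximal-scoring subsegment under break-even scoring at
   the identity threshold (match `1 - 0.70`, mismatch `-0.70` — no new
   parameter), which trims exactly the unsupported terminal stretches that
   otherwise count against base-level precision; `refine_boundaries =
   FALSE` restores the plain maximal-run rule. Elements shorter than
   `min_length = 100` bp are discarded.
6. **Copy-number filter.** Each element is searched against both genomes of
   the focal pair; more than `max_hits = 4` hits in either genome removes
   it (exactly 4 survives — the boundary is inclusive). This is what keeps
   unannotated repeat copies out of the element set.

## Search and E-values

The cross-genome search uses exact word seeds of size 6 and ungapped x-drop
extension, reporting the best hit per (query, species) under an E-value
ceiling of 1e-6, with `E = K * m * n * exp(-lambda * S)`; `m` is the query
length and `n` the searched genome's total ungapped length summed over
sequences. Two deliberate choices:

* **Two-hit seeding.** Pure 6-mer seeding is quadratic noise on random
  sequence; the internal seeder requires two non-overlapping word hits on
  the same diagonal within 40 bp before extending, which preserves
  sensitivity for >= 100 bp, >= 70% identity targets while keeping runtime
  sane. `single_hit = TRUE` restores classic seeding.
* **Karlin–Altschul constants.** `lambda` solves
  `sum p_i p_j exp(lambda * s_ij) = 1` by bisection to 1e-9 (~1.33 for
  +1/−2 on uniform background). `K` uses the closed form valid when the
  gcd-reduced maximum score is +1 — `K = (1 − e^(−λ'))·E[S'·e^(λ'S')]` on
  the reduced lattice — which reproduces the published ungapped BLASTN
  constants (+1/−2: 0.62; +1/−1: 1/3). Score systems outside that family
  fall back to a conservative `K = 0.3` with a warning. Ungapped constants
  are applied to the (rare) gapped imports as the standard practical
  approximation. Extension is ungapped; on substitution-only cohorts this
  is exact, and decision margins are enormous (planted hits score far
  above the E-value cut-off, neutral sequence far below).

Hit counting for copy-number questions (`count_hits`,
`count_hits_matrix`) relaxes best-hit bookkeeping and merges overlapping
hits per strand before counting, since best-hit settings mask true copy
number.

## Ancestral inference, dating, zones

Elements detected in the clade-1 reference pair are ancestral when present
in at least one clade-2 species, and vice versa; such elements were
necessarily inherited from the two clades' common ancestor. Clade-2
elements overlapping a kept clade-1 element are dropped. Open points fixed
here: overlap is tested *first in the clade-1 reference species* through
the element's best hit there, falling back to any shared species; >= 1 bp
same-strand overlap merges, keeping the clade-1 record. Dating follows
outgroup precedence: any vertebrate-outgroup hit -> vertebrate-age, else a
gar-analog hit -> Neopterygian, else 3R. The category partition is
exhaustive and disjoint by construction, so category counts always add up
to the repertoire size — the same bookkeeping the package applies to the
reported repertoire counts shipped in
`inst/extdata/teleost_reported_counts.tsv`.

Zone profiling tiles each reference chromosome into 500 kb windows (the
terminal partial window counts as a zone, which is what makes zone totals
reproducible from chromosome lengths); an element belongs to the zone
containing its start (config-switchable to midpoints). Zone classes:
`empty`, `vertebrate-containing`, `novel-neopterygian` (Neopterygian
present, no vertebrate), `novel-3R` (3R only).

The conservation score is the mean pairwise column identity across present
species, computed in the element's coordinate frame — a deliberately simple
stand-in for model-based conservation scoring, sufficient for ordering age
classes when substitution-rate constraints differ by age.

## Target association and the bootstrap null

Candidate genes are all genes whose body overlaps hit ± 1 Mb, in every
species where the element is present; distance is the gap to the gene body
(0 for intronic elements). An orthogroup's synteny score is the number of
supporting species; its proximity rank is the mean, over those species, of
its best member's 1-based rank by increasing distance, with fractional
ranks for distance ties (the averaging is over species containing the
pair, not all species — the natural reading when absence carries no rank).
Targets are selected by score >= 5 species, then maximum score, then
minimum rank, retaining exact ties; associations are `ancestral` when any
selected orthogroup belongs to the vertebrate-CNE target set.

The bootstrap null re-draws, per associated element and replicate, a random
gene set *of the size of its selected target list*, uniformly without
replacement from the reference species' gene complement (10,000 replicates;
z = (observed − mean)/sd). Resampling candidate-list-sized subsets instead
would saturate at desk scale: a 1 Mb window spans most of a simulated
chromosome, so nearly every random subset contains an ancestral-orthogroup
gene and the null collapses to its ceiling; target-list-sized draws keep
the null informative at any genome size and still match the exhaustive
enumeration used in the tests.

The calibration shuffle permutes *labels*, not positions: a random
orthogroup set of the same size replaces the vertebrate-CNE target set, the
real associations are reclassified, and the mean z over five draws is
reported (expected |z| < 2). Position shuffling is also available
(`mode = "positions"`) but carries a small systematic positive bias at desk
scale: anchor genes sit in cleared neighbourhoods (a layout needed for
unambiguous nearest-gene truth), so a nearest-gene pick from a random
position is catchment-area-weighted toward anchors while the bootstrap null
draws genes uniformly. The label permutation destroys the
element/ancestral-target association while holding geometry fixed on both
sides of the comparison.

## Paralogy and phylogenomics

Duplicated elements are found by searching each element against the element
set's own sequences (not the genome, so repeat contamination cannot create
spurious pairs); any above-threshold nonself hit is an edge candidate
(reciprocity is not required). An edge is kept only when the two elements'
selected targets are the same gene or annotated paralogs; connected
components form clusters, dated `pre-WGD` if any anchoring paralog relation
predates the WGD, `post-WGD` if all postdate it, and `mixed` otherwise — a
third class added for anchor conflicts that a two-class scheme leaves
unaddressed. Cluster sets from two reference groups are intersected by
anchor orthogroups.

Phylogenomic markers are elements with *exactly one* hit in every species
of the design (with or without the gar analog); copy number comes from the
relaxed hit counter, since best-hit search masks it. Marker sequences are
best-hit coordinates ± 50 bp, projected into the element frame (exact for
ungapped hits; clipped flanks are gap-padded), concatenated, trimmed at
> 50% column gap fraction, and passed to neighbor joining on p-distances
with pairwise deletion (Jukes–Cantor correction available). Topologies are
compared by unrooted Robinson–Foulds distance. Maximum-likelihood inference
is deliberately out of scope; markers can be exported for external tools,
and an MSA hook (`msa_fun`) accommodates unaligned real-data markers.

## The simulator: what it emulates and what it does not

`sim_config()` defaults define the study conditions: seven species on a
fixed, roughly clock-like tree — a vertebrate outgroup (root depth ~0.7
neutral substitutions/site), a gar analog, and five teleost-analog species
in two basal clades (clade 1: `zeb`, `tet`; clade 2: `til`, `fugu`,
`seab`), with both focal pairs ~0.8 apart. At that depth neutral sequence
sits near 50% identity — below both the aligner's score threshold and the
70%/100 bp rule — while planted elements (age-graded rate scalings 0.06 /
0.10 / 0.14 of neutral) stay above 85% identity between focal species.
The age grading encodes the expectation that older, more broadly conserved
elements are under stronger constraint; it is also what makes the
conservation-score ordering (vertebrate > Neopterygian > 3R) a planted,
testable property.

The root genome is 4 chromosomes x 600 kb carrying 200 genes (4 exons of
150 bp each, exon rate scale 0.15). 120 elements of 150–300 bp are planted
in clusters flanking anchor genes: 12 ancestral anchors host vertebrate-age
elements and ~85% of the younger ones (`ancestral_target_frac`, so old and
new elements largely reuse target loci), 4 novel anchors host only gained
elements (producing novel zones), and 3 ancient gene pairs host
vertebrate-age element pairs with identical starting sequence (2R-analog
paralogy). Anchors keep a 15 kb clearance from other genes so that each
element's nearest gene is its true target — the property that makes
planted-target recovery well-defined. A 30-copy, 400 bp interspersed
repeat family evolves slowly (rate scale 0.05, a young active family), with
only ~70% of copies annotated, so the copy-number filter has real work to
do. The TAATTA consensus is written centrally into 20% of elements at
birth and kept under strong constraint (rate scale 0.02).

Per branch, in order: WGD (teleost stem; chromosomes duplicate, gene copies
retained with probability 0.3, element copies with probability 0.25 and
only alongside their anchor's copy, pre-WGD pair anchors always reverting
to single copy so each gene carries one paralogy relation class), element
births (vertebrate at the root, Neopterygian on the gar+teleost stem, 3R on
the teleost stem after the WGD), whole-element losses (probability 0.05
per living element per branch), inversions (Poisson, mean 0.5 per branch,
30–150 kb, breakpoints in feature-free gaps), optional neutral indels
(off by default), then Jukes–Cantor substitution.

Deliberate simplifications, and hence what passing tests do *not* show
about real data: substitution-only evolution by default (no indel
realism — alignments of real genomes are gappy and fragmented);
transposons as a single slow consensus family rather than bursts of
lineage-specific insertions; uniform base composition and no
isochore/GC structure; clean annotations (real exon/repeat tracks are
incomplete in less curated genomes); losses as clean whole-element
deletions (a `divergence_events` mode instead raises an element's rate to
neutral on one branch, emulating gain-by-divergence, but is off by
default); and truth-derived stand-ins for the external vertebrate CNE
reference set and its targets.

## Numerical and degenerate-input conventions

Coordinates are uniformly 0-based half-open internally; conversions happen
only at format boundaries (GFF3 and AXT are 1-based inclusive, BED native;
minus-strand AXT query coordinates are normalised to the forward strand on
read). Sequence characters outside `ACGTN` are uppercased and mapped to
`N` with a warning; `N` runs are auto-added to the repeat annotation
(hard-masked inputs are honoured). Bisection for lambda runs to 1e-9;
select-target ties use an 1e-9 tolerance on proximity ranks; best-hit ties
break by lowest E, then highest score, then lexicographic (chrom, start).
Empty inputs return typed empty tables rather than errors, except where
the contract demands a hard failure (element beyond chromosome end, missing
genome for a species, unaligned markers without an MSA hook). Every
stochastic stage takes an explicit seed; stage seeds are derived from the
master seed by a stable hash kept below 2^31.

## Problem sizes

The shipped defaults (7 species, 2.4 Mb root genome, 120 planted elements)
run the full pipeline in about 1.5 minutes on one core; the test suite
exercises the acceptance properties on five seeds of the default cohort
plus a smaller two-chromosome cohort for module tests. These sizes were
chosen so that the whole validation cycle stays interactive while keeping
every statistic (recall, precision, category accuracy, bootstrap z, RF
distance) estimated from at least ~100 planted elements.

## Known limitations

* The internal aligner and search are ungapped; real-genome use is expected
  to go through imported AXT alignments, and search sensitivity on
  indel-rich targets is untested.
* The conservation score orders age classes but is not calibrated to any
  model-based score.
* Bootstrap z-scores inherit the usual normal-approximation caveats when
  the ancestral gene fraction is extreme (sd near 0 is flagged as
  degenerate).
* Zone statistics on the simulated cohort rest on ~16 zones; they validate
  the bookkeeping, not the biology of zone clustering.
* The `mixed` paralogy origin class absorbs anchor conflicts; no attempt is
  made to resolve them by molecular clocks or synteny blocks.
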