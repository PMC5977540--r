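---
title: "Methods behind waspcomp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind waspcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waspcomp)
```

waspcomp packages the small, self-contained computations of a
parasitoid-wasp draft-genome study. This vignette explains the model behind
each stage, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the decisions taken where the
underlying procedures are conventionally under-specified.

## Genome size from a k-mer spectrum

A k-mer spectrum counts distinct k-mers (k = 17 by default, the standard
choice for insect-sized genomes: 4^17 comfortably exceeds any insect genome,
while k stays short enough for per-read sampling) by their sequencing
depth. Depths of single-copy genomic k-mers are approximately Poisson
around the mean coverage, so the spectrum shows a signal peak near the mean
depth, while base-calling errors generate a large population of near-unique
k-mers piled up at depth 1–2. The estimator is

$$\widehat{G} = \frac{\sum_{d \ge d_{\min}} d\,c(d)}{d_{\text{peak}}},$$

with $c(d)$ the distinct-k-mer count at depth $d$ and $d_{\text{peak}}$
the argmax of $c$ at $d \ge d_{\min}$. Numerator: total sequenced k-mer
mass attributable to the genome. Denominator: per-copy depth. Two
conventions needed fixing:

* **Error cutoff `d_min`.** Standard spectrum practice, adopted here, is
  the first local minimum of the count curve — the valley between the
  error pile-up and the signal peak. Implementation: the first depth bin
  at which counts start rising again, scanning upward. A spectrum with no
  rise is either pure signal (its support starts above depth 2; `d_min`
  is then its smallest depth) or a pure error curve (monotonically
  decreasing from depth 1–2), for which the estimator refuses to guess and
  raises an error. `d_min` is always overridable.
* **Peak depth is the mode, not a fitted Poisson mean.** The mode is
  deterministic and assumption-free; its price is ±1 granularity in the
  denominator (roughly 2% at depth 50), visible in the worked example in
  the README. The recovery tests budget for exactly this: ≤ 5% relative
  error at depth 50 with 30% error k-mers.

Invariances tested: scaling all counts by a constant scales the estimate
by the same constant and leaves the peak depth unchanged.

## Genome size from flow cytometry

Propidium-iodide flow cytometry measures relative DNA content as a
fluorescence-channel position. With an internal standard of known DNA
amount co-prepared with the sample,

$$\text{amount}_{\text{sample}} =
  \text{amount}_{\text{ref}} \times
  \frac{\bar{c}_{\text{sample}}}{\bar{c}_{\text{ref}}},$$

where $\bar{c}$ is the event-weighted mean channel inside a user-supplied
gate. The estimate inherits the ploidy of the gated sample peak:
wasp males are haploid (1C) and females diploid (2C), and published
analyses routinely relate a 1C male peak to a 2C female peak, so any
factor-of-2 conversion must be a visible, deliberate step. Peaks therefore
carry explicit `"1C"`/`"2C"` tags and `flow_genome_size()` never converts
between them. The formula is invariant under a common channel rescaling
(detector gain), which is tested. Gates are caller-chosen; overlapping or
miscentred gates are a usage concern, not an error, as in standard
cytometry software.

`fold_coverage()` is plain division of sequenced bases by genome size;
display truncation to an integer "X" happens only at the reporting layer.

## Windowed GC and CpG observed/expected

Windows are non-overlapping, 500 bp by default; trailing partial windows
are dropped rather than rescaled so every reported window has identical
sampling variance. Per window,

$$\text{CpG ratio} = \frac{P[\mathrm{CpG}]}{P[\mathrm{C}]\,P[\mathrm{G}]},$$

with mononucleotide frequencies over valid (ACGT) positions and the CpG
dinucleotide frequency over valid adjacent pairs (both positions ACGT,
consecutive, within the window — no cross-window pairs, keeping windows
independent). Conventions that the published description leaves open and
were fixed here: positions in N (or any non-ACGT symbol, which the loaders
map to N with a warning) are excluded from both numerator and denominator
rather than discarding whole windows; the ratio is reported as missing when
$P[\mathrm{C}]\,P[\mathrm{G}] = 0$. CpG is counted on the given strand
only; as a dinucleotide class CpG is its own reverse complement, so this
is presentation-neutral. With a 500 bp window the denominator uses
within-window frequencies, which makes individual window ratios noisy
(the ratio is a quotient of estimates); only window averages are
interpreted, and the tests check means, not single windows.

`assembly_stats()` uses the standard N50: the length of the shortest
sequence in the smallest descending-length prefix holding at least half
the total assembly length. It is validated against a brute-force prefix
enumeration on random instances.

## BRH orthology and the similarity score

Orthologous counterparts are best reciprocal hits between two proteomes
after a strict e-value filter (`evalue < 0.01`; a hit at exactly 0.01 is
excluded). "Best" for a query is the highest bit score, with ties broken
by lower e-value and then by lexicographically smallest subject id — the
last rule exists purely to make results reproducible across input
orderings. Self-pairs (identical ids) are excluded. Each pair carries

$$\text{similarity} = \frac{\text{alignment length}}
  {\min(\text{query length}, \text{subject length})}
  \times \frac{\%\text{identity}}{100},$$

the aligning ratio times fractional identity. The ratio may exceed 1 for
gapped alignments longer than the shorter protein; the score is reported
as-is rather than clamped. Sequence lengths come from the FASTA files, not
from the hit lines, and a pair whose lengths cannot be resolved is a hard
error rather than a silent drop.

## Microsynteny blocks

Anchors are the 1:1 ortholog pairs placed on each species' per-scaffold
gene order (dense ordinal indices by start coordinate, ties by gene id).
Two anchors are linked when they share a scaffold in each species and are
separated by at most `max_gap` intervening genes (index difference minus
one, counted on the scaffold's full gene list, so non-ortholog genes do
interrupt) in **both** species. Blocks are connected components of this
link graph with at least `min_anchors` anchors. Defaults `min_anchors = 3`,
`max_gap = 5` are the rule used in wasp microsynteny comparisons.

Three genuinely open points, decided as follows:

* **Gap enforcement in one or both species.** Symmetric enforcement was
  chosen as the stricter reading that is also invariant to swapping the
  species; the detector takes its rule from `synteny_params`, so a user
  disagreeing can relax `max_gap` but not the symmetry.
* **Clustering, not collinearity.** Blocks are proximity clusters; whether
  the anchor order is identical or exactly reversed between species is
  computed per block and reported as the `order_consistent` flag rather
  than being a filter. The consensus gene-order *fraction* (syntenic
  pairs / all ortholog pairs) is the block-membership summary.
* **Determinism.** Blocks are ordered by (scaffold, first index), anchors
  within a block by species-A index, so outputs are byte-stable.

The detector is validated two independent ways: against an exhaustive
pairwise-linking + depth-first component oracle on 200 random small
instances, and by exact recovery of planted scenarios (below). Monotonicity
properties (more gap allowance never loses syntenic pairs; a higher anchor
threshold never adds blocks) are tested as well.

## miRNA target consensus

Five target predictors report incompatible binding-site coordinates, so
relations are keyed by the (miRNA, gene) pair and the consensus is the
exact intersection across all per-tool sets — a relation survives only if
every tool predicted it. The operation is checked against a naive
occurrence-counting oracle and for the lattice properties of
intersection (consensus of one set is the set; adding a set never grows
the consensus; the consensus never exceeds the smallest set).

## What the synthetic generators emulate

All generators are pure functions of their parameters and a mandatory
seed (the caller's RNG stream is restored afterwards).

* `simulate_genome()` draws a first-order Markov chain whose stationary
  base composition equals the target GC exactly and whose CpG rate is
  `cpg_depletion` times the iid expectation $P(C)P(G)$: the C→G
  transition is thinned by the depletion factor and the removed G mass is
  redistributed to the other predecessors so the stationary distribution
  is preserved. It emulates composition, not biology: no repeats, no
  isochores, no coding structure, no N runs. Passing composition tests on
  it says the window arithmetic is right, not that real genomes behave
  like a first-order chain.
* `simulate_kmer_spectrum()` draws zero-truncated Poisson depths for
  `genome_size_bp` distinct k-mers (truncation conserves the distinct
  count, matching the estimator's view that every genomic k-mer is
  observed) and adds an error component at depths 1–2 (70/30 split)
  sized so error k-mers are the requested fraction of all distinct
  k-mers. It deliberately is not a read simulator: no GC bias, no
  repeat-induced multi-copy peaks, no heterozygosity shoulder — the
  estimator only consumes the histogram, and those effects are exactly
  what the recovery tests are not claiming to cover.
* `simulate_flow_histogram()` is a mixture of integer-rounded Gaussian
  peaks; no debris continuum or doublet artefacts, so gating is trivial
  by construction.
* `simulate_ortholog_scenario()` plants blocks that satisfy the detection
  rule in both species (consecutive anchors `gap_genes` apart) and places
  each additional noise ortholog so that, in species A, it is more than
  `max_gap` genes from every other anchor on its scaffold — a noise
  anchor therefore cannot link to anything, and the detectable block set
  equals the planted truth exactly. The construction is deterministic
  with a final validator pass re-checking both guarantees; an impossible
  packing (too many genes requested per scaffold) errors rather than
  silently bending the layout. Defaults (100 genes and 2 scaffolds per
  species, 2 blocks of 4 anchors with 2-gene gaps, 5 noise pairs) keep
  the default scenario well inside feasibility.
* `simulate_hit_tables()` gives every true pair reciprocal high-bit-score
  hits at `evalue_true` and sprinkles spurious low-score hits at
  `evalue_spurious`, discarding any reciprocal spurious pair so BRH
  output equals the truth exactly at the default cutoff.
* `simulate_target_sets()` builds one shared core of
  `round(consensus_fraction × n_relations)` relations plus tool-specific
  fillers that no two tools share, making the all-tools intersection the
  core by construction.

## Numerical and testing choices

Problem sizes in the test suite were chosen so the statistical checks are
sharp at desk scale: 1 Mb genomes for composition means (≈ 2000 windows),
10^5 k-mers × 20 seeds for spectrum recovery at ≤ 5% relative error,
10^4 events per flow peak × 20 seeds at ≤ 1%, 200 random instances for
each brute-force oracle comparison and 50 seeds for planted-block
recovery. One statistical subtlety: the *mode* of a sampled Poisson
histogram with integer mean is intrinsically a toss-up between adjacent
bins (the Poisson pmf is equal at λ−1 and λ, and neighbouring bins differ
by less than sampling noise at 10^5 draws), so the generator test asserts
the mode within ±2 of the mean depth and leaves accuracy claims to the
size-recovery criterion, which is the quantity that matters and is tested
at its stated tolerance.

## Known limitations

* The spectrum estimator has no heterozygosity or repeat correction; on
  real spectra with a heterozygous shoulder the automatic `d_min` can land
  in the shoulder and the mode-based peak underestimates coverage.
* The flow estimator trusts the caller's gates; it does not find peaks.
* Synteny detection assumes strict 1:1 pairs (it rejects multi-hits and
  points at the BRH stage); tandem duplications and many-to-many
  orthology are out of scope.
* Genome-scale published results that require the original proteomes,
  reads or assemblies (the 135 Mb spectrum estimate from real reads,
  the 351/346 block counts, N50s of the real assembly) are outside what
  the package can recompute; only their desk-scale arithmetic and the
  statistical behaviour of the methods on synthetic data are validated.
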