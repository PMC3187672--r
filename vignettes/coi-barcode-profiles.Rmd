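---
title: "COI barcode profiles: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{COI barcode profiles: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiprofile)
```

## The problem

Many insect groups — aphids prominently among them — contain species that
cannot be told apart morphologically. Distance-based DNA barcoding sidesteps
this by exploiting the *barcode gap*: within a species, mitochondrial COI
sequences typically differ by well under 1 %, while different species within
a genus typically differ by several percent. If the two distributions do not
overlap, a short COI fragment identifies specimens to species, and
departures from the pattern are themselves informative: unusually deep
divergence *within* a nominal species suggests cryptic lineages, and
unusually shallow divergence *between* nominal species suggests synonymy or
subspecies status.

`coiprofile` implements this workflow: K2P distances, a neighbor-joining
(NJ) similarity profile, intraspecific/interspecific divergence
partitioning, alignment site statistics, and delimitation flags, plus a
simulator that generates data with the same statistical structure and full
ground truth.

## The distance model

For two aligned sequences, sites are classified as transitions (A↔G, C↔T)
or transversions (any purine↔pyrimidine change), giving observed
proportions $P$ and $Q$ over the $n$ compared sites. The Kimura
two-parameter distance is

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

an estimate of the expected number of substitutions per site under a model
with separate transition and transversion rates. K2P is the standard metric
at barcoding depths, where distances are small and transition bias in
mitochondrial DNA is strong.

Numerical and data-handling choices:

* **Deletion mode.** The default is *pairwise* deletion: a column is
  skipped for a pair if either sequence carries a gap, `N` or an ambiguity
  code. This preserves information when GenBank-derived fragments are
  unevenly trimmed. *Complete* deletion (drop such columns set-wide) is
  provided for exact cross-checks against tools that default to it; which
  mode a published study used is often undocumented, and per-pair means can
  differ slightly between the two.
* **Ambiguity codes** are treated as missing, not resolved
  probabilistically — resolving them would bias the estimator by guesses.
* **Saturation.** When either log argument is non-positive the distance is
  undefined. Such pairs are marked `NA`, carried with their $P, Q$
  diagnostics, excluded from all summary means, and counted in the run log.
  Silently zeroing or clamping them would corrupt table means.
* **Units.** Internally every divergence is a proportion; report writers
  multiply by 100 and print two decimals with half-up rounding. A sample
  standard deviation over pairwise divergences is printed, with `/` when
  only a single pair exists.

## The NJ profile

The tree is built with the standard Saitou–Nei agglomeration (join the
pair minimizing $Q(i,j) = (r-2)\,d_{ij} - R_i - R_j$). Two behaviors that
vary silently between implementations are pinned down:

* **Ties** in the Q criterion are broken by the lexicographically smallest
  sorted label pair, making output identical across platforms.
* **Negative limb lengths**, which NJ can produce, are clamped to zero with
  the deficit transferred to the sibling limb; each clamp is logged.
  Downstream cohesion logic assumes non-negative lengths.

The tree is treated strictly as a similarity profile: no bootstrap, no
outgroup rooting, no claim about deep relationships. All downstream logic
operates on the *unrooted bipartition set*, avoiding any rooting choice.

## Divergence partitioning

Every pair of ingroup specimens is intraspecific (same species),
interspecific (same genus or "group of species", different species) or
cross-group; the three classes are exhaustive, so their counts sum to
$m(m-1)/2$. The per-species table includes species with exactly two
individuals (a single pair, SD undefined). The per-group table supports two
modes:

* **representative** (default): one seeded-random individual represents
  each species — the classic protocol when species are unevenly sampled.
  The seed is recorded, making the draw reproducible; averaging over seeds
  converges to the species-level all-pairs mean (tested).
* **all-pairs**: every cross-species individual pair contributes. Published
  per-group ranges sometimes exceed what single representatives could
  give, so both modes are exposed.

The "All" interspecific row pools all between-species pairs among ingroup
species regardless of group, which is how survey-wide interspecific means
are usually quoted. The histogram bins both series into shared half-open
bins from zero (default width 0.5 %); a positive barcode gap appears as
disjoint occupied bins.

## Site statistics

Columns are classified over unambiguous bases only: constant (one state),
variable (≥ 2 states), parsimony-informative (≥ 2 states each in ≥ 2
sequences), singleton (variable but not informative). A column with fewer
than two unambiguous cells supports no comparison and is excluded from the
tally (reported separately). Base composition is the arithmetic mean of
per-sequence frequencies, not pooled counts — the convention behind "mean
composition" figures; the two differ when sequences have unequal numbers of
ambiguous cells.

## Delimitation diagnostics

* **Cohesion**: a species is cohesive when its specimens form one side of
  some bipartition of the unrooted tree (single specimens by convention).
  Corner case worth knowing: because the complement of a single leaf is
  itself a side, a species comprising all but one leaf of the tree is
  cohesive by this definition; with realistic multi-species data sets the
  case does not arise.
* **Conspecific clades**: the specimens of one species are partitioned into
  the minimal number of maximal single-species bipartition sides —
  deterministic, and a direct measure of how fragmented a species is in
  the profile.
* **Flags**: species whose maximum conspecific divergence reaches the
  *split threshold* (default 2 %) are cryptic-species candidates; same-group
  species pairs whose mean cross-species divergence is at or below the
  *merge threshold* (default 1.5 %) are synonymy/subspecies candidates. The
  defaults reflect the empirical contrast between typical intraspecific
  (< 1 %) and reported cryptic-split (≈ 2.6–3 %) divergences in aphid COI
  surveys; both are plain parameters, because such judgments are
  qualitative in the literature. A cohesive species whose nearest split
  neighbors (union over all minimal covering splits, since ties occur
  around the serialization root) all belong to a different declared group
  is flagged *misplaced*. All flags are advisory; nothing is renamed.

## The simulator: what it emulates, and what not

`sim_config()` states the simulated world once:

| parameter | default | why |
|---|---|---|
| `n_species` | 12 | desk-scale analog of a ~36-species survey |
| `individuals_per_species` | 5 | uneven 1–53 sampling supported via a range |
| `seq_length` | 591 | typical analyzed COI fragment length (bp) |
| `interspecific_range` | 0.035–0.08 | the range in which most congeneric divergences fall |
| `intraspecific_depth` | 0.01 | within-species divergences mostly below 1 % |
| `kappa` | 4 | realistic insect-mtDNA transition/transversion rate ratio |
| `base_weights` | A .345, C .139, G .122, T .394 | strong A/T bias of insect COI |
| `n_groups` | 3 | genus-level grouping at desk scale |
| `cryptic_fraction`, `cryptic_depth` | 0, 0.028 | planted deep splits at the magnitude reported for cryptic aphid lineages |

The species tree is ultrametric with node heights drawn so every
between-species path depth lands inside `interspecific_range`; individuals
attach as shallow stars (cryptic species as two subclades separated by
`cryptic_depth`). Sequences evolve by the exact per-branch K2P transition
probabilities (closed form, not event simulation) — exact and fast at this
scale. All randomness derives from one master seed through named
substreams, so a configuration is a reproducible fixture.

Deliberate non-realism, and hence what a green test does *not* establish:
no indels (the fragment is treated as gap-free coding sequence), no
among-site rate variation, no composition drift (the AT bias enters through
the root draw only; the K2P process preserves it only approximately), no
outgroup lineages, and groups are perfect clades. Tests against simulated
data validate the machinery — estimator consistency, tree recovery,
partition accounting, flag logic — not the biological values of any real
survey, which additionally depend on alignment-window and deletion-mode
choices that published studies often leave undocumented.

## Degenerate inputs and determinism

Alignments need ≥ 2 records, unique non-empty ids, equal lengths and the
nucleotide/IUPAC/gap alphabet; violations are errors that name the
offender. Window coordinates are 0-based half-open everywhere. Pairs with
no comparable sites are undefined, like saturated pairs. `run_profile()`
writes each output atomically, embeds no timestamps, and seeds every
random choice from the configuration, so a rerun reproduces the bundle
byte for byte; tables are pure views recomputable from the emitted
distance matrix.
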