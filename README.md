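# coiprofile

Distance-based species identification from aligned mitochondrial COI
barcode fragments, built for groups — such as aphids — where morphology
alone cannot separate species reliably.

The package implements the classic barcoding workflow as composable,
tested pieces:

* **K2P distances.** For each sequence pair the observed transition
  proportion *P* (A↔G, C↔T) and transversion proportion *Q* are turned
  into the Kimura two-parameter divergence

  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

  with pairwise or complete deletion of gapped/ambiguous columns and
  explicit marking (never silent zeroing) of saturated pairs.
* **NJ profile.** A Saitou–Nei neighbor-joining tree with a deterministic
  tie-break and non-negative (clamped, logged) branch lengths, used as a
  similarity profile rather than a deep phylogeny.
* **Divergence partitioning.** Pairwise divergences split into
  intraspecific and interspecific sets, summarized per species and per
  genus/"group of species" (mean, range, sample SD, in percent), pooled
  statistics, and a shared-bin histogram that makes the barcode gap —
  intraspecific mostly < 1 %, interspecific mostly 3.5–8 % — visible.
* **Site statistics.** Constant / variable / parsimony-informative column
  counts and mean per-sequence base composition.
* **Delimitation flags.** Tree-based cohesion (a species is cohesive when
  its specimens form one side of a bipartition of the unrooted tree),
  enumeration of conspecific clades, and threshold flags for
  cryptic-species candidates (deep intraspecific divergence), synonymy
  candidates (shallow interspecific divergence) and misplaced taxa.
* **Synthetic data.** A K2P sequence simulator over a random ultrametric
  species tree with full ground truth (true tree, true distances, planted
  cryptic splits), so the whole pipeline is testable offline.

## Worked example

```r
library(coiprofile)

# simulate a small barcode study: 12 species, 5 specimens each, 591 bp
ds <- simulate_coi_dataset(sim_config(seed = 1))
ds$alignment
#> coi_alignment: 60 sequences x 591 sites

dm   <- k2p_distances(ds$alignment)
tree <- neighbor_joining(dm)

tab1 <- intraspecific_summary(dm, ds$taxonomy)
round(tab1[tab1$taxon == "All", -1], 2)
#>    n_individuals n_pairs mean range_min range_max   sd
#> 13            60     120 0.54         0      1.89 0.36

tab2 <- interspecific_summary(dm, ds$taxonomy, seed = 1)
round(tab2[tab2$taxon == "All", -1], 2)
#>   n_species n_individuals n_pairs mean range_min range_max   sd
#> 3        12            60      66 6.98      2.77     10.85 1.84

coh <- cohesion_report(tree, ds$taxonomy)
sum(coh$cohesive)
#> [1] 12
```

The pooled intraspecific mean (0.54 %) sits far below the interspecific
mean (6.98 %) and every one of the 12 species forms its own cohesive
cluster in the NJ profile: a clean barcode gap. `run_profile()` executes
the same chain end-to-end and writes the distance matrix, Newick tree,
divergence tables, histogram, site statistics and delimitation flags as a
reproducible TSV bundle; `inst/cli/coiprofile.R` exposes it as a command
line (`profile`, `simulate`, `distances`, `tree` subcommands).

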