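# homodist

Distance-ordered homoplasy tracing for phylogenetics and species
delimitation.

## What it does

Homoplasy — similarity among taxa that is not inherited from a common
ancestor (convergence, reversal, horizontal transfer) — is the noise of
parsimony-based tree assessment, and it grows both with the number of taxa
and with the evolutionary distance a tree spans. For short taxonomic
markers (fungal ITS, LSU D1/D2 rDNA), two questions matter in everyday
taxonomic practice: at what distance does homoplasy begin to appear, and
can the stability of homoplasy *within* a species, against its jumps
*between* species, serve as auxiliary evidence for species delimitation?

`homodist` answers both with an incremental taxon-addition procedure.
From one aligned multi-FASTA file it:

1. computes all pairwise distances (F84 by default; K80, JC69, raw
   alternates),
2. picks a **center** — the taxon with the lowest average distance to all
   others — or accepts one chosen by the user,
3. orders all taxa by increasing distance from the center,
4. builds a first tree from the center and its three nearest neighbors,
   then adds one taxon per step, and at every step builds neighbor-joining
   and UPGMA trees and scores them with Fitch parsimony.

Each step records the new taxon's distance from the center (`disCen`), the
maximum pairwise distance of the current set (`MaxD`), and per tree the
parsimony sums and indices

- CI = M/S — consistency index (minimum changes over required changes),
- HI = 1 − CI — homoplasy index,
- RI = (G − S)/(G − M) — retention index (`NA` when undefined),
- RCI = CI·RI, and
- **SHI = HI/MaxD** — the specific homoplasy index, homoplasy normalized
  by the distance span of the current tree.

Downstream analyses locate the first step where HI becomes positive,
correlate CI with distance over the steps showing homoplasy, and partition
the taxon series into groups of constant HI — plateaus that typically
coincide with species blocks.

## Worked example

All data are synthetic with known ground truth: a 10-taxon random
coalescent tree, a 300-site alignment whose every variable site fits that
tree perfectly, plus 5 injected convergent sites (same derived base given
to two unrelated clades) that are guaranteed to carry homoplasy.

```r
library(homodist)

tree <- random_binary_tree(10, seed = 7)
aln  <- simulate_homoplasy_free_alignment(tree, n_sites = 300,
                                          n_mutations = 90, seed = 8)
aln  <- inject_convergent_sites(aln, tree, k = 5, seed = 9)

trace <- run_homodist(aln)          # F84 distances, auto center, NJ + UPGMA
dplyr::select(tidy(trace), step, added_taxon, n_taxa, disCen, MaxD,
              nj_CI, nj_HI, nj_SHI)
#> # A tibble: 7 × 8
#>    step added_taxon n_taxa disCen   MaxD nj_CI  nj_HI nj_SHI
#>   <int> <chr>        <int>  <dbl>  <dbl> <dbl>  <dbl>  <dbl>
#> 1     1 t5               4 0.0722 0.0722 1     0       0
#> 2     2 t8               5 0.0723 0.0759 1     0       0
#> 3     3 t4               6 0.0906 0.132  1     0       0
#> 4     4 t2               7 0.0944 0.136  1     0       0
#> 5     5 t7               8 0.113  0.140  0.974 0.0260  0.185
#> 6     6 t6               9 0.117  0.160  0.955 0.0449  0.280
#> 7     7 t10             10 0.144  0.189  0.95  0.0500  0.264
```

The trace starts at CI = 1 (no homoplasy) and HI switches on at step 5 —
exactly when the second carrier of the injected convergent state enters
the taxon set:

```r
first_homoplasy_step(trace)
#>    step added_taxon n_taxa disCen  MaxD     HI
#> 1     5 t7               8  0.113 0.140 0.0260

ci_distance_correlation(trace)      # Pearson r over steps with CI < 1
#> [1] -0.9088935

delimit_hi_groups(trace)
#> HI partition (nj tree): 4 group(s)
#>   group 1 (HI = 0.0000): t9, t3, t1, t5, t8, t4, t2
#>   group 2 (HI = 0.0260): t7
#>   group 3 (HI = 0.0449): t6
#>   group 4 (HI = 0.0500): t10
```

CI falls almost linearly as the spanned distance grows (r ≈ −0.91), and
the HI partition separates the homoplasy-free core from the taxa that
bring convergent signal in — the pattern that, on real markers, flags
species transitions. `autoplot(trace)` draws the CI/HI/SHI and distance
series; `write_trace_tsv()` and `write_trace_trees()` export the step
table and per-step Newick trees. A thin command-line wrapper with `run`,
`groups`, `correlate` and `simulate` subcommands is installed at
`inst/scripts/homodist`.

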