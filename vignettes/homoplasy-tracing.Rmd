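---
title: "Tracing homoplasy along a distance-ordered taxon series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing homoplasy along a distance-ordered taxon series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homodist)
```

## The problem

Homoplasy — character-state similarity that does not come from common
ancestry — arises from convergent evolution, reversals and horizontal gene
transfer, and it accumulates as phylogenetic trees grow in taxa and in the
distances they span. On a given tree it is quantified by parsimony indices:
the consistency index CI = M/S (minimum possible character changes over
changes actually required), its complement the homoplasy index HI = 1 − CI,
and the retention index RI = (G − S)/(G − M), the fraction of apparent
synapomorphy retained, where G is the worst-case (star-tree) step count.

For short taxonomic markers such as the fungal ITS and LSU D1/D2 rDNA
regions, two practical questions follow. First, at what evolutionary
distance does homoplasy start to matter for a tree built from these
markers? Second, since HI tends to be stable within a species and to jump
when a new species enters the analysis, can HI changes serve as auxiliary
evidence for species delimitation? This package implements the incremental
procedure designed to answer both: order all taxa by distance from a
central taxon, grow the tree one taxon at a time, and watch the indices.

## The procedure

Given one aligned multi-FASTA file (the sole input):

1. Compute the full pairwise distance matrix (F84 by default).
2. Choose the **center**: either automatically, as the taxon with the
   lowest average distance to all others, or a taxon fixed by the user
   (`auto_center`/`center`, mirroring the classic `autCen`/`defCen`
   argument names, which the config-file reader accepts verbatim).
3. Order the remaining taxa by ascending distance from the center, ties
   kept in input order.
4. Build the first tree from the center plus its three nearest neighbors;
   then add one taxon per step until the series is exhausted. At every
   step, cluster the distance submatrix with neighbor joining and UPGMA,
   score the sub-alignment on each tree with Fitch parsimony, and record:
   - `disCen`: the distance of the newest taxon from the center;
   - `MaxD`: the maximum pairwise distance within the current taxon set;
   - `S`, `M`, `G`, `CI`, `RI`, `HI`, `RCI` per tree;
   - `SHI = HI / MaxD`, the specific homoplasy index, i.e. homoplasy
     normalized by the distance span of the current tree (set to 0 when
     `MaxD = 0`, where no distance has been spanned at all).

Both `disCen` and `MaxD` are nondecreasing along the trace by
construction. The trace is fully deterministic: all tie-breaks are
documented, and no randomness is involved anywhere in the engine.

Downstream, three analyses consume the trace:

- `first_homoplasy_step()` reports the earliest step with HI > 0. Because
  "the distance at which homoplasy appeared" can mean either the entering
  taxon's distance from the center or the span of the current subset, both
  `disCen` and `MaxD` are reported for that step.
- `ci_distance_correlation()` gives the Pearson correlation between `MaxD`
  and CI over the steps with CI < 1; steps with CI = 1 carry no
  information about the homoplasy–distance relationship. With fewer than
  3 qualifying steps, or zero variance, the correlation is reported `NA`
  rather than a misleading number.
- `delimit_hi_groups()` partitions the taxon series at HI change points:
  the center and the three taxa of the first tree share the first step's
  HI, each later taxon carries the HI of its entry step, and a new group
  opens whenever HI changes. HI plateaus typically span conspecific
  strains; changes tend to fall at species transitions. Groups are
  evidence for delimitation, not automatic species decisions.

## Distance model

The default distance is the F84 closed form, with
A = π~C~π~T~/π~Y~ + π~A~π~G~/π~R~, B = π~C~π~T~ + π~A~π~G~, C = π~R~π~Y~:

d = −2A·ln(1 − P/(2A) − (A−B)·Q/(2AC)) + 2(A−B−C)·ln(1 − Q/(2C)),

where P and Q are the observed transition and transversion proportions.
Design choices a user reconciling against other tools should know:

- **Base frequencies** are estimated once from the whole alignment, not
  per pair, so the distance matrix stays consistent across taxon subsets
  and the matrix can be computed once and sliced per step.
- **Missing data** ('-', '?', any IUPAC ambiguity code) are handled by
  pairwise deletion, which preserves signal in partially gapped rDNA
  alignments. Pairwise deletion also makes every pairwise distance
  independent of the taxon subset, which is what justifies slicing.
- **Saturation** (a non-positive logarithm argument) yields a flagged
  `NA` with a warning, never a fabricated value; the trace engine refuses
  to order taxa through undefined distances and stops with an error
  naming the offending pair.
- Distances are proportions internally; the percentage scale used in
  reports and plots is 100 times that.
- Under uniform base frequencies the F84 expression reduces algebraically
  to the K80 two-parameter distance; the test suite verifies this
  reduction numerically to below 1e−10 over a (P, Q) grid, and checks all
  four models (`F84`, `K80`, `JC69`, `raw`) against an independent
  reference implementation (`ape::dist.dna`) to machine precision.

## Tree building and parsimony conventions

Neighbor joining (Saitou–Nei, via ape) and UPGMA (average-linkage
`hclust`, node heights at half the merge distance) are both computed at
every step and all indices are reported side by side, with NJ as the
headline method. Any negative NJ branch lengths are retained internally
and clamped to zero only at Newick serialization; parsimony scoring uses
the topology alone, and the Fitch count is invariant to the arbitrary
rooting of the unrooted NJ tree. Newick output orders every node's
children by smallest contained leaf label, so identical topologies always
serialize identically and per-step tree files are diffable across runs.
Agglomeration tie-breaks inside NJ/UPGMA are delegated to the underlying
implementations, which are deterministic for a fixed input order; exact
ties are measure-zero for the continuous distances used here.

Parsimony scoring follows these conventions:

- CI sums over **all** sites, uninformative ones included (they add
  equally to M and S). MEGA/PAUP-style "excluding uninformative" variants
  will differ; reconcile by subtracting the invariant-site contribution.
- Gaps and `?` are **missing data** carrying the full base set
  {A, C, G, T}, never a fifth state; IUPAC ambiguity codes carry their
  base sets. The Fitch pass operates on these sets directly, so missing
  data never force a change.
- S = 0 (no change required anywhere) gives CI := 1, HI := 0 — required
  so that a series of near-identical strains shows a clean "no homoplasy"
  plateau instead of a 0/0.
- RI is reported `NA` (never 0) when G = M, i.e. when no character is
  parsimony-informative and "apparent synapomorphy" is undefined.
- G, the star-tree maximum, is computed set-aware: the minimum over
  central bases of the number of taxa whose base set excludes that base.
  On unambiguous data this equals the familiar "scored taxa minus largest
  state class"; with ambiguity codes the unambiguous-only count can fall
  below the Fitch length S, which would make RI negative, so the
  set-aware form is used throughout to preserve M ≤ S ≤ G.

## HI-group comparison precision

Parsimony step counts are integers but CI is a ratio, so two steps that
are "the same" biologically can differ in the 12th decimal through
floating-point division. `delimit_hi_groups()` therefore compares HI
after rounding to 4 decimals by default — well below any biologically
meaningful HI difference on markers of a few hundred sites, where one
extra step moves HI by order 1/S ≈ 0.01 — with `digits = Inf` available
for exact comparison.

## What the synthetic generator does and does not emulate

The package validates itself on constructed data with known ground truth:

- `simulate_homoplasy_free_alignment()` assigns each variable site to
  exactly one edge of a random coalescent tree; every variable column
  then fits the generating topology in exactly one step, so CI = 1 is an
  **exact** oracle by construction, not a probabilistic one (rejection
  sampling was deliberately avoided).
- `inject_convergent_sites()` appends columns whose derived state is
  shared by two disjoint clades whose union is not a split of the tree.
  Each such column needs at least two changes on the true topology while
  its minimum is one — a provable per-site homoplasy guarantee. This
  models convergence; horizontal-transfer-style segment swaps would be a
  future extension.
- `simulate_f84_sequences()` runs the actual F84 Markov process along
  branches (rate matrix normalized to one expected substitution per unit
  length, transition-probability matrices by matrix exponential), used to
  confirm that estimated distances recover true path lengths.

What this synthetic data does **not** contain: indels and alignment
error, rate heterogeneity across sites, base-composition drift across
lineages, and the concerted evolution of multi-copy rDNA arrays. Passing
tests therefore demonstrate the correctness of the algorithmic machinery
on data satisfying the models' assumptions; they do not certify behavior
on real rDNA alignments, where alignment quality and intragenomic
variability add noise the models ignore.

## Validation problem sizes

The shipped test suite exercises: Fitch scoring against an exhaustive
ancestral-assignment oracle on 200 random trees/columns with up to 6
taxa (including missing and ambiguous states); 100 seeded homoplasy-free
runs with 6–12 taxa and 100–300 sites asserting exact CI = 1 traces;
NJ recovery of additive matrices for 4–8 taxa, with a full least-squares
topology-enumeration oracle at 4–5 taxa; UPGMA exactness on ultrametric
matrices; F84 distance recovery on ten simulated 10,000-site pairs within
three standard errors; and the structural trace invariants (length
n − 3, monotone `disCen`/`MaxD`, HI = 1 − CI, SHI·MaxD = HI, M ≤ S ≤ G)
on every run. These sizes keep the whole suite under a minute while the
oracles remain exhaustive where exhaustiveness is the point.

## Known limitations

- Only unweighted, unordered (Fitch) characters; no tree search — indices
  are computed on the given NJ/UPGMA trees, which is the point of the
  method, not a shortcut.
- No maximum-likelihood distances, gamma rate heterogeneity, or protein
  models; saturated pairs are refused rather than imputed.
- The center heuristic (minimum average distance) matches the method's
  definition but is not claimed optimal for delimitation sensitivity; the
  trace depends on the center at short range by design, converging across
  centers only once the taxon set (and hence the tree) coincides.
- Alignment computation is out of scope: the engine consumes pre-aligned,
  equal-length FASTA and offers only optional gap-flank trimming
  (`trim = TRUE`), off by default since inputs are assumed pre-trimmed.
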