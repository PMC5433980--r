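---
title: "Methods: fungal-host diversity and overlap in mycoheterotroph communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fungal-host diversity and overlap in mycoheterotroph communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoverlap)
```

## The scientific problem

Mycoheterotrophic (MH) plants obtain carbon from arbuscular-mycorrhizal
fungi instead of supplying it, so each fungal OTU a plant exploits is a
*host* in an antagonistic interaction. Framed in niche terms, a plant's
fungal-host set defines a niche whose **width** can be measured as the
phylogenetic diversity (PD) of the host set, while **overlap** between
plants is the fraction of hosts they share. This package operationalises
both, for single plants and for groups, and provides the inference layer
that asks whether diversity and overlap rise together and whether
co-occurrence at a locality structures them.

## Diversity of a single plant's host set

Faith PD of a host set is the total branch length of the minimal subtree of
the fungal phylogeny spanning those OTUs. Two conventions had to be fixed:

- **Stem exclusion.** The spanning subtree *excludes* the edge above the
  set's most recent common ancestor; equivalently PD is the unrooted
  spanning length. Under this convention the PD of the full leaf set equals
  the tree length without any root stem, and a singleton set has PD 0. The
  alternative (including a stem or the path to the root) shifts every PD by
  a bounded amount and would cancel almost entirely in the min–max scaled
  quantities the analysis actually uses.
- **Scaling.** Raw PD grows mechanically with the number of hosts, so each
  observed value is located inside the exact attainable range at its host
  count: PD′ = (PD − PDmin)/(PDmax − PDmin), extremes taken over *all*
  equal-size subsets of the fungal pool.

Enumerating those subsets is impossible at realistic sizes (C(138, 42) ≈
10^38), and uniform sampling cannot find extremes of such a space. The
package therefore computes both extremes **exactly**:

- **Maximum PD** by greedy leaf addition seeded with the tree-diameter
  pair. The greedy algorithm is provably optimal for maximum PD on trees
  and its solutions are nested, so one pass yields the maxima for every
  size at once. Ties (equal attachment gains, or several diameter pairs)
  are broken toward the lexicographically smallest leaf label so results
  are deterministic.
- **Minimum PD** by dynamic programming: each node carries, for every j,
  the minimal total edge length of a connected subgraph rooted there
  containing j leaves of its clade; children are folded in by min-plus
  convolution and the answer is minimised over candidate ancestor nodes.
  Any connected subgraph contains the spanning subtree of its leaves, and
  the bound is attained at the true MRCA, so the minimum over nodes is
  exact. Complexity is O(n·k²), trivial at n = 138, k ≤ 42.

Both algorithms are verified in the test suite against exhaustive
enumeration on 200+ random trees of 8–12 leaves for every feasible subset
size, using an independent oracle (the closed-tour identity: visiting a
subset's leaves in the tree's planar circular order walks every spanning
edge exactly twice). `sample_pd_range()` provides a Monte-Carlo band that
must bracket inside the exact extremes, as an additional invariant.

Ultrametricity is not required by any computation; host trees from
time-calibrated analyses are simply branch-length trees here.

## Sharing measures and group statistics

With d_i the host count of plant i and C_ij the shared-host count:

- count dissimilarity |d_i − d_j| (signal on niche *width*),
- presence-form Bray–Curtis 1 − 2C_ij/(d_i + d_j),
- min-overlap C_ij/min(d_i, d_j) — sharing relative to the most a pair
  *could* share; 1 exactly when one host set nests in the other.

For a group, the combined PD is the Faith PD of the pooled host set, and
the group overlap is the **mean** pairwise min-overlap. A summed form of
the same statistic appears in the field; within a fixed group size the two
differ by the constant pair count, so min–max scaling inside a same-size
ensemble is *identical* under either — an equivalence asserted in the test
suite. The mean is preferred because it stays on [0, 1] and comparable
across sizes.

Group metrics are scaled within the **ensemble of all C(S, n) groups** of
the same size n over the species pool S; observed field communities are
scaled against the generated ensemble of their size, placing them inside
the range of what the species pool allows. A degenerate range (all groups
identical on a metric) yields NA rather than a value, and every downstream
statistic treats NA as "degenerate", never as zero.

Sampling-effort covariates per group: total specimens, pooled OTU count
and the Herfindahl index of specimens across members (Σ shares²; 1/s for s
equally sampled members). These enter the partial correlations.

## Inference layer

- **Mantel tests** correlate upper triangles of two pairwise matrices and
  permute the rows/columns of one of them jointly; the alternative is
  one-sided ("greater") with p = (count + 1)/(n_perm + 1), the convention
  of vegan's `mantel`, against which the implementation is cross-checked.
  Default 10^4 permutations. The min-overlap matrix is a similarity; the
  pipeline correlates phylogenetic distance with 1 − overlap so all three
  sharing matrices enter as dissimilarities. Per-locality tests rerun the
  same machinery on each locality with ≥ 3 species, using the species-wide
  host sets (location-restricted host sets would need specimen-level
  incidence, which the species-level pipeline deliberately collapses).
- **Correlations** between scaled PD and scaled overlap: Pearson r with a
  t-distribution p (df = n − 2), per group size and pooled across sizes;
  partial Pearson via residual projection on the covariates plus intercept
  (df = n − 2 − q). The pipeline needs a *plant* phylogeny only for the
  Mantel stage, so that input is optional and the stage is skipped with a
  note when absent.
- **Location comparisons**: a group is "same location" iff a single
  locality's sampled-species set contains every member (existential over
  localities — a species may occur at several). Welch's unequal-variance
  t-test with a 95% CI of (same − different) compares scaled PD and scaled
  overlap between the two categories, per size. Welch is chosen over
  Student because the same-location category is far smaller and has no
  reason to share a variance with its complement.
- No multiple-testing correction is applied anywhere; the result tables
  report raw p-values side by side.

Two caveats the package makes explicit rather than hiding: the C(S, n)
group records overlap in membership, so their nominal p-values understate
dependence (the tests are descriptive of the ensemble, not of independent
replicates); and location contrasts must be read **per size** — pooling
sizes flips signs by composition, because same-location groups concentrate
at small sizes whose scaled overlap is lower.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of a
location-structured MH survey; its defaults are the package's study
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_plants`, `n_fungi` | 20, 138 | the survey scale the pipeline targets |
| `n_localities`, `multi_species_localities` | 15, 9 | sites, of which 9 host ≥ 2 species |
| `multi_species_counts` | 6,6,5,4,2,2,2,2,2 | per-site species richness; the richest sites hold 4–6 co-occurring species, enough to support the observed community sizes and per-site tests |
| `host_count_range` | 2–42 | observed span of hosts per species; drawn log-uniform to reproduce the heavy right skew without asserting an empirical distribution |
| `locality_pool_size` | 45 | each site exposes roughly a third of the regional 138-OTU pool — a realistic locality-scale richness for AM fungi |
| `pool_sharing` | 0.9 | probability a host draw comes from the local pool; near 1 is the regime a location-structured survey implies, 0 switches the mechanism off |
| `specimens_per_species_range` | 1–10 | specimens per population record |
| `community_sizes` | 2,2,3,3,3,5 | observed co-occurring communities |

The host-acquisition mechanism mirrors the field process: hosts are drawn
*population by population*, each locality occurrence sampling that
locality's own fungal pool (with probability `pool_sharing`; otherwise the
full OTU set). Species that co-occur therefore share hosts through the
pool they both tap. An earlier design that pooled a species' localities
before sampling diluted exactly this signal and was replaced. With
heterogeneous host counts and a finite pool, both a pair's overlap and its
pooled PD grow with the members' d values, which induces the positive
diversity–overlap association across groups; setting `pool_sharing = 0`
removes the location effect while leaving the d-driven association intact.
Locality pools are uniform draws by default; `clumped_pools = TRUE`
over-represents a random clade per site for probing the scaled-PD
machinery under phylogenetic clustering.

Trees (host and plant) are pure-birth, rescaled to unit depth, so branch
lengths are in relative time units. One master seed is split into named
sub-seeds (tree, localities, hosts, specimens, communities), so each
sub-generator is independently reproducible and `generate_tree(cfg)`
matches the tree inside `generate_dataset(cfg)`.

What the generator does **not** emulate: read-level noise and OTU-calling
error; abundance information (incidence is binary by design, since hosts
are counted, not weighted); phylogenetic signal in the plant phylogeny
(host sets are independent of plant relatedness, so Mantel tests are
expected null); spatially explicit co-occurrence below the locality grain;
and any fitting to a particular real survey. Passing tests on generated
data therefore demonstrate that the pipeline recovers structure *of the
kind assumed*, not that any particular field system has that structure.

## Numerical choices and degenerate inputs

- Branch-length tolerances: floating comparisons in the extremal
  algorithms use relative 1e-12 (1e-9 at reconstruction), and round-trip
  Newick I/O preserves lengths to 1e-9 via 12 significant digits.
- Ties: greedy leaf addition and the DP backtrack both break ties toward
  the lexicographically smallest label / smallest allocation, making every
  extremal set deterministic.
- Degenerate inputs degrade to flags, never crashes: constant matrices in
  Mantel, constant or all-NA vectors in correlations, zero-variance pairs
  in Welch, and collapsed min–max ranges in scaling all return explicit
  `degenerate`/NA results, and the full pipeline runs end-to-end on a
  dataset where every plant has the same host set.
- Permutation p-values are (count + 1)/(n_perm + 1), bounded below by
  1/(n_perm + 1), and all stochastic operations accept an explicit seed;
  equal seeds give bit-identical results.

## Problem sizes in the test suite

The suite verifies exact-algorithm equivalence on 200 random trees of 8–12
leaves across all subset sizes; calibrates the Mantel test's type-I error
at n = 10, 999 permutations, 500 replicates (empirical rejection at
α = 0.05 required in [0.03, 0.07]); and runs the structure-recovery checks
at the full default scale (20 plants × 138 fungi, all 21,679 groups of
sizes 2–5) over six generator seeds, contrasting `pool_sharing = 0.9`
against 0. These sizes were chosen to make every probabilistic assertion
comfortably stable while keeping a complete run around a minute.

## Known limitations

- The per-plant scaled PD of uniformly drawn host sets concentrates in the
  upper half of its range (tight clades are rare by chance), so the
  generator reproduces "most plants above 0.5" structurally; it cannot
  test a plant's *departure* from uniform host choice.
- Observed-community inference is over very few communities (six by
  default); its correlation is reported with df = n − 2 but is best read
  descriptively.
- Species-level incidence discards within-species, between-locality host
  variation; per-locality Mantel tests consequently use species-wide host
  sets.
- The ensemble records are combinatorially dependent; treat ensemble-level
  p-values as descriptive (see above).
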