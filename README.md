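# mycoverlap

Quantifying how mycoheterotrophic (MH) plants share and diversify their
arbuscular-mycorrhizal fungal hosts.

Fully mycoheterotrophic plants have abandoned photosynthesis and draw carbon
*from* their mycorrhizal fungi, turning the usual mutualism into exploitation
of a fungal "host". For a community of such plants, two quantities frame
their niche structure:

- **fungal-host diversity** — how phylogenetically spread out the fungal
  OTUs exploited by a plant (or a group of plants) are, and
- **fungal-host overlap** — how much different plants tap the same fungi.

`mycoverlap` implements the full analysis pipeline for plant × fungus
incidence surveys of this kind, together with a synthetic-data generator so
every stage can be exercised and tested without field data.

## The statistics at the core

For plant *i*, let *d<sub>i</sub>* be its number of fungal hosts and
*C<sub>ij</sub>* the hosts shared with plant *j*.

- **Faith PD** of a host set: total branch length of the minimal subtree of
  the fungal phylogeny spanning those OTUs (stem edge above their MRCA
  excluded; singleton sets have PD 0).
- **Scaled PD**: PD′ = (PD − PD<sub>min</sub>) / (PD<sub>max</sub> −
  PD<sub>min</sub>), where the extremes range over *all* subsets of the
  fungal pool with the same number of hosts. The package computes these
  extremes **exactly**: greedy leaf addition from the tree-diameter pair
  (provably optimal) for the maximum, and an O(n·k²) dynamic program over
  the tree for the minimum — no Monte-Carlo approximation is needed even
  for C(138, 42) subset spaces, although `sample_pd_range()` offers one as
  a cross-check.
- **Pairwise sharing**: count dissimilarity |d<sub>i</sub> − d<sub>j</sub>|,
  presence-form Bray–Curtis 1 − 2C<sub>ij</sub>/(d<sub>i</sub> + d<sub>j</sub>),
  and the min-overlap measure C<sub>ij</sub>/min(d<sub>i</sub>, d<sub>j</sub>).
- **Group statistics**: the combined PD of a group's pooled host set and
  the mean pairwise min-overlap, min–max scaled within the ensemble of
  *all* C(S, n) groups of the same size n drawn from the S-species pool.
- **Inference**: one-sided permutation Mantel tests of plant phylogenetic
  distance against each sharing measure (phylogenetic signal), Pearson and
  partial Pearson correlations between scaled PD and scaled overlap
  (controlling for sampling effort, OTU richness and the Herfindahl
  concentration of specimens), and Welch comparisons between groups whose
  members all co-occur at one locality and groups whose members do not.

## Worked example

Simulate a survey with the package's default study conditions (20 plant
species, 138 fungal OTUs, 15 localities of which 9 host several species,
host counts 2–42, locality-pooled host acquisition) and run the whole
analysis:

```r
library(mycoverlap)

cfg <- synthetic_config(seed = 1)
ds  <- generate_dataset(cfg)
report <- run_analysis(ds$host_tree, ds$incidence, ds$metadata, ds$communities,
                       plant_tree = ds$plant_tree, group_sizes = 2:5,
                       n_perm = 10000, seed = 1)
report
#> diversity-overlap analysis: 20 plants, 138 fungi
#>   group ensembles: sizes 2,3,4,5, 21685 groups (6 observed communities)
#>   pooled scaled PD ~ scaled overlap: r = 0.645, df = 21677, p = 0
#>   global Mantel (host_count/bray_curtis/overlap): r = -0.080/0.037/0.038
```

The pooled correlation says that across all 21,679 generated groups,
groups of plants that share more of their fungal hosts also span a larger
slice of the fungal phylogeny — the diversity–overlap association the
locality-pooled generator builds in. The small global Mantel r values say
the plant phylogeny explains neither host counts nor host sharing (the
generator encodes no phylogenetic signal).

Same-location groups share more hosts at every group size:

```r
report$location_tests[report$location_tests$metric == "scaled_overlap",
                      c("n", "mean_same", "mean_diff", "p.value", "ci_low", "ci_high")]
#>       n mean_same mean_diff    p.value ci_low ci_high
#>   <int>     <dbl>     <dbl>      <dbl>  <dbl>   <dbl>
#> 1     2     0.273     0.197 0.0242     0.0102   0.143
#> 2     3     0.399     0.282 0.0000164  0.0669   0.166
#> 3     4     0.492     0.344 0.00000593 0.0915   0.204
#> 4     5     0.590     0.406 0.00243    0.0788   0.288
```

Per-plant scaled PD locates each species' observed host set inside the
exact range attainable at its host count (a 10 KB synthetic fixture ships
with the package):

```r
fx <- read_fixture(system.file("extdata", "synthetic_survey", package = "mycoverlap"))
run_analysis(fx$host_tree, fx$incidence, fx$metadata, fx$communities,
             plant_tree = fx$plant_tree, group_sizes = 2:3,
             n_perm = 10000, seed = 42)$per_plant
#> # A tibble: 6 × 6
#>   plant_id     d    pd pd_min pd_max scaled_pd
#>   <chr>    <int> <dbl>  <dbl>  <dbl>     <dbl>
#> 1 plant_01     5  3.54 1.13     4.57     0.701
#> 2 plant_02     2  1.04 0.0220   2.00     0.516
#> 3 plant_03     7  4.77 1.98     5.68     0.754
#> 4 plant_04     7  4.11 1.98     5.68     0.578
#> 5 plant_05     3  2.91 0.258    2.91     1.00
#> 6 plant_06     7  4.64 1.98     5.68     0.719
```

`plant_05`'s three hosts happen to be the most phylogenetically dispersed
triple the 20-OTU pool allows (scaled PD = 1); `plant_02` sits mid-range.
`autoplot(report)`, `plot_location_comparison(report)` and
`plot_per_plant(report)` give ggplot views of these tables, and
`report_tables(report, dir)` exports everything as TSV + JSON.

Analysing real data works the same way: read a Newick fungal phylogeny
with `read_host_tree()`, a 0/1 incidence TSV with `read_incidence()` (or
long-format specimen records with `read_long_records()`), metadata and
communities with their readers, check the bundle with `cross_validate()`,
and call `run_analysis()`.

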