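# thermidr

Do thermophilic bacteria carry fewer intrinsically disordered proteins
(IDPs) because of their growth temperature, or because of who their
ancestors were? `thermidr` is an R package for studying how proteome-level
intrinsic disorder relates to the optimal growth temperature (OGT) of
bacterial species **while controlling for shared ancestry**. It is aimed at
molecular-evolution and comparative-genomics researchers who have protein
sequences, per-protein (or per-residue) disorder scores, and a species
phylogeny — or who want to validate the whole workflow on synthetic data
with known ground truth.

## What it computes

**Sequence composition and the diagram of states.** For each protein the
package computes the fraction of positive residues f⁺ (K, R), negative
residues f⁻ (D, E), the fraction of charged residues FCR = f⁺ + f⁻, the net
charge per residue NCPR = f⁺ − f⁻, and mean Kyte–Doolittle hydropathy
normalized to [0, 1]. Sequences are classified into the five regions of the
charge diagram of states: weak polyampholytes/polyelectrolytes
(FCR < 0.25), boundary/Janus sequences (0.25 ≤ FCR ≤ 0.35), strong
polyampholytes (FCR > 0.35, |NCPR| ≤ 0.35), and negative/positive strong
polyelectrolytes (|NCPR| > 0.35, dominated by acidic or basic residues).

**IDP candidate filtering.** A protein is an IDP candidate when at least
one rule fires: whole-protein disorder score ≥ 0.5; residues × score ≥ 100
(a disordered-mass rule); or diagram-of-states region 3, 4 or 5. A bundled
charge–hydropathy heuristic (logistic distance from the boundary
|NCPR| = 2.785·⟨H⟩ − 1.151) supplies whole-protein scores offline;
per-residue score files from any external predictor can be read instead.

**Ortholog clustering.** Greedy incremental clustering in the CD-HIT style:
proteins sorted by decreasing length join the first cluster whose
representative they match at global-alignment identity ≥ 0.7
(Needleman–Wunsch, identity relative to the shorter sequence). Clusters are
retained when they span ≥ 10 species and contain ≥ 1 candidate IDP.

**Species tree.** Identity distances from aligned 16S sequences (pairwise
deletion of gapped columns), UPGMA construction (always ultrametric),
outgroup pruning, Newick round-trip.

**Quasi-independent contrasts.** Internal-node trait states x̂ minimize the
residual sum of squares

    RSS = Σ_branches (x_child − x_parent)² / b_branch

with leaves fixed at observations — a positive-definite quadratic solved
exactly (each internal state is the 1/b-weighted mean of its neighbors).
For every internal node the contrast is the difference between its two
children's values, standardized by √(b_left + b_right). FOD contrasts are
regressed on OGT contrasts through the origin:
slope = Σxy/Σx², R² about zero, two-sided p on n − 1 df.

**Group statistics.** Thermophile (OGT ≥ 40 °C) vs mesophile split, mean ±
SE FOD tables by diagram-of-states class / function tag / cluster, Welch
t-tests, ordinary least squares, and ranking of clusters by absolute
thermophile–mesophile FOD difference with aligned, moving-average-smoothed
(window = length/30) disorder tracks.

**Synthetic data.** Coalescent species trees; Brownian-motion OGT/FOD
traits with a tunable evolutionary slope and a tunable one-clade OGT shift
(pure phylogenetic confounding); Jukes–Cantor 16S-like sequences;
composition-templated proteomes spanning all five regions, optionally with
planted ortholog families.

## Worked example

```r
library(thermidr)

classify_das_pappu(compute_composition(c("KKDKKGGGGG", "EEKKDRKEDE", "GGSSTTAAVV")))
#>   length f_plus f_minus fcr ncpr region                       region_label
#> 1     10    0.4     0.1 0.5  0.3      3               strong polyampholyte
#> 2     10    0.4     0.6 1.0 -0.2      3               strong polyampholyte
#> 3     10    0.0     0.0 0.0  0.0      1 weak polyampholyte/polyelectrolyte

cfg    <- sim_config(seed = 7, n_species = 8)   # null: no OGT–FOD relationship
tree   <- simulate_tree(cfg)
traits <- evolve_traits(tree, cfg)

contrasts <- compute_contrasts(tree, traits)
contrasts
#> # A tibble: 7 × 6
#>    node weight delta_ogt std_ogt delta_fod  std_fod
#>   <int>  <dbl>     <dbl>   <dbl>     <dbl>    <dbl>
#> 1     9  1.17       5.68    4.84  0.0207    0.0176
#> 2    10  1.01      13.0    12.9   0.0242    0.0239
#> 3    11  0.364      1.68    4.62 -0.000980 -0.00270
#> # ℹ 4 more rows

contrast_regression(contrasts)
#> <origin_fit: slope = -0.00127785 (SE 0.00141), R2 = 0.1203, t(6) = -0.906, p = 0.4, n = 7>
```

One standardized (ΔFOD, ΔOGT) pair is produced per internal node (7 pairs
for 8 species). Under this null simulation the origin-fixed slope is small
and non-significant (p = 0.4), exactly what the contrast analysis should
report when disorder does not track temperature once ancestry is removed.
`tidy()`/`glance()` give the fit as tibbles; `autoplot()` draws the
contrast scatter; `plot_diagram_of_states()` shows proteins in the (f⁻, f⁺)
plane.

The full pipeline — simulation, composition, candidate filtering,
clustering, group tables, 16S tree, contrasts, divergent-cluster tracks —
runs from one call (or from the shell via `scripts/run_pipeline.R`):

```r
res <- run_pipeline("pipeline_out", seed = 1)
```

All outputs are plain-text tables plus a provenance JSON, and are
byte-identical across reruns with the same seed.

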