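---
title: "Disorder, growth temperature, and phylogeny: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disorder, growth temperature, and phylogeny: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermidr)
```

## The question the package addresses

Across bacteria, proteome-level intrinsic disorder appears to decline as
optimal growth temperature (OGT) rises. But species are not independent
observations: close relatives share both their OGT and their proteome
composition by descent, so a naive regression of disorder abundance on OGT
can be driven entirely by phylogenetic structure. `thermidr` implements the
comparative workflow needed to separate the two explanations — sequence
composition metrics, disorder-based candidate filtering, ortholog
clustering, tree building, and quasi-independent contrasts — together with
a synthetic-data generator that makes every step testable against known
ground truth.

## Composition metrics and the five-region classification

For a sequence of length $L$, $f^+$ is the fraction of lysine and arginine,
$f^-$ the fraction of aspartate and glutamate, $\mathrm{FCR} = f^+ + f^-$
and $\mathrm{NCPR} = f^+ - f^-$. Histidine is treated as neutral — the pH-7
convention of the diagram-of-states framework; its charge at physiological
pH is small and including it would blur the region boundaries. `X` (unknown
residue) carries zero charge and the Kyte–Doolittle midpoint. Mean
hydropathy is normalized to $[0,1]$ via $(\mathrm{KD} + 4.5)/9$, the
convention of charge–hydropathy plots.

Region boundaries are 0.25 and 0.35 on FCR and 0.35 on $|\mathrm{NCPR}|$.
The literature describes the regions qualitatively, so the exact boundary
membership is a package decision, made once and tested exhaustively:
$\mathrm{FCR} = 0.25$ and $0.35$ belong to the boundary region (region 2),
and $|\mathrm{NCPR}| = 0.35$ belongs to the strong polyampholytes
(region 3). With $f^+ + f^- \le 1$, the five predicates provably cover the
reachable simplex disjointly (if $|\mathrm{NCPR}| > 0.35$ then the minority
charge fraction is below $0.325$, so regions 4 and 5 cannot overlap); a
grid sweep in the test suite confirms full, single coverage at a 0.01
resolution.

## Disorder scores and the candidate filter

The package treats disorder prediction as an injected score source:
per-residue score files from any external predictor are read from TSV
(`position`, `residue`, `score`), validated for contiguity and range, and
reduced to the fraction of disorder (FOD) as the fraction of residues with
score at or above a threshold. The threshold defaults to 0.5 and is
inclusive; it is a parameter because published per-residue predictors
differ in whether their binary calls are thresholded at 0.5 or tuned.
For whole-protein-only scores, FOD is the score itself.

As a bundled, dependency-free default the package ships a
charge–hydropathy heuristic: the signed distance of a sequence from the
boundary $|\mathrm{NCPR}| = 2.785\,\langle H\rangle - 1.151$ mapped through
a logistic with steepness 10, so the boundary itself scores exactly 0.5.
The steepness only sets how quickly scores saturate away from the boundary;
ordering and the 0.5 crossing are the semantically meaningful properties.
This is a composition-only heuristic, not a modern machine-learned
predictor: it makes the pipeline runnable and testable offline, and it is
deliberately invariant under residue shuffling. A windowed variant
(default window 15 residues, forced odd) provides per-residue tracks.

The candidate filter is a disjunction of three rules: whole-protein score
$\ge 0.5$; length $\times$ score $\ge 100$ (at least ~100 expected
disordered residues — catches long, moderately disordered proteins); or
diagram-of-states region 3, 4 or 5. Both thresholds are inclusive and
exposed as parameters.

## Clustering

`greedy_cluster()` reproduces the incremental CD-HIT scheme at desk scale:
proteins are sorted by decreasing length (ties by id) and each joins the
first cluster whose representative it matches at identity $\ge 0.7$, else
founds a new cluster. Identity comes from an exact Needleman–Wunsch global
alignment (match $+1$, mismatch $0$, linear gap $-0.5$; traceback ties
resolved toward the diagonal) with the number of identical aligned
positions divided by the shorter sequence's length — CD-HIT's global
identity convention. CD-HIT's k-mer prefilter, banded alignment and
threading are intentionally not reproduced; on borderline pairs results may
therefore differ from CD-HIT, whose short-word filter can reject pairs the
exact DP accepts. Cluster retention requires $\ge 10$ species and $\ge 1$
candidate IDP.

## Species tree

Distances between aligned 16S sequences are $1 -$ (identical columns /
comparable columns), where a column is comparable when neither sequence has
a gap (pairwise deletion — the least-assumption choice when the upstream
aligner is external). A Jukes–Cantor correction
$d = -\tfrac34\log(1 - \tfrac43 p)$ is available but off by default, since
raw identity distances are the stated input convention. UPGMA is built on
`stats::hclust(method = "average")` (average linkage with node height half
the merge distance), which is deterministic including on ties; output trees
are ultrametric to floating-point precision and verified so in tests.
Outgroup handling drops the outgroup leaf and merges the two branches at
the resulting degree-2 node, preserving all ingroup path lengths.

## Ancestral states and quasi-independent contrasts

Internal-node states minimize
$\mathrm{RSS}(x) = \sum_{\text{branches}} (x_c - x_p)^2 / b$, with leaves
fixed at the observed trait values. The objective is a positive-definite
quadratic; its unique minimizer satisfies, at each internal node, that the
state equals the $1/b$-weighted mean of its tree neighbors, and is obtained
exactly by solving the internal block of the weighted graph Laplacian.
Because the literature for this method does not print the objective's
weighting, an unweighted option (all $b = 1$) is also provided; the
$1/b$-weighted form is the default since it matches branch-proportional
Brownian variance. Zero-length branches (possible under UPGMA tie merges)
are replaced by $10^{-8}\times$ tree height before weighting.

Contrasts are computed at every internal node of the (binary) tree as the
difference between its two children's values — observed at leaves, inferred
elsewhere — with children ordered deterministically (left child = the one
whose subtree contains the lexicographically smallest leaf label).
Standardization divides by $\sqrt{b_l + b_r}$; both raw and standardized
contrasts are returned, and the regression uses standardized contrasts by
default. Multifurcations are resolved into zero-length caterpillars with a
warning.

A deliberate divergence from Felsenstein's recursive independent contrasts:
no branch lengthening is applied to propagate the estimation variance of
inferred states, because the method implemented is a single global RSS fit
rather than the recursive pruning algorithm. The measurable consequence,
documented by the property tests, is that standardized contrasts from pure
Brownian traits are exactly calibrated at cherries (two leaf children;
pooled variance within 10% of $\sigma^2$) but mildly shrunk where inferred
states enter (pooled variance over all nodes $\approx 0.87\,\sigma^2$ on
64-leaf coalescent trees). This shrinkage does not bias the slope of the
origin-fixed regression, and its type-I error stays at the nominal level
(measured 0.049 over 1000 null replicates at the default conditions).

The contrast regression fixes the intercept at the origin — a zero OGT
contrast predicts a zero FOD contrast — with slope $\sum xy / \sum x^2$,
$R^2$ computed about zero, and a two-sided $t$ test on $n - 1$ degrees of
freedom. Degenerate inputs are explicit errors (all-zero $x$) or explicit
`NA`s rather than silent numbers.

## Group statistics

Species with OGT $\ge 40$ °C (boundary inclusive) are thermophiles. Group
summaries report mean FOD, its standard error (sample SD/$\sqrt n$;
reported as 0 with a flag at $n = 1$) and $n$ per class/tag/cluster and
group, with explicit "absent" rows when a group has no members. Two-group
comparisons default to the Welch test (unequal $n$ and variance are the
norm here) with the pooled Student variant behind a flag; inputs where both
groups have zero variance raise a degenerate-input error rather than
returning a silent p-value, since on synthetic data that almost always
signals a misconfigured generator.

## Aligned disorder tracks

Per-residue scores are smoothed on the ungapped sequence with a centered
moving average whose window is length/30 (floored, clamped to $\ge 1$,
forced odd by adding 1 so the center is defined), truncating at the edges
(divisor = actual neighborhood size). Smoothing precedes projection through
alignment gaps: smoothing across gap columns would average scores of
non-homologous positions. Clusters are ranked by the absolute difference
between mean thermophilic and mesophilic FOD, excluding clusters missing
either group.

## The synthetic-data generator

The generator produces every input the pipeline reads, with known truth:

* **Trees**: random binary coalescent trees rescaled to height 1
  (`tree_height`). Coalescent topologies give the deep root splits typical
  of bacterial phylogenies.
* **Traits**: Brownian motion. Per branch of length $b$, the OGT increment
  is $N(0, \sigma_{\mathrm{OGT}}^2 b)$ and the FOD increment is
  `true_slope` times the OGT increment plus independent
  $N(0, \sigma_{\mathrm{FOD}}^2 b)$ noise, so the contrast-level regression
  has expectation `true_slope` by construction. Brownian motion is chosen
  because contrasts are exact under it, making parameter recovery a valid
  acceptance surface. Defaults: root OGT 35 °C with $\sigma_{\mathrm{OGT}} =
  10$ °C per unit branch (a TEMPURA-like spread in which both mesophiles
  and thermophiles occur), root FOD 0.15 with $\sigma_{\mathrm{FOD}} =
  0.05$ (FOD means on the scale reported for bacterial proteomes). FOD is
  treated as an unbounded quantitative trait; no clamping to $[0,1]$ is
  applied, as clamping would break the Brownian assumptions the contrasts
  rely on.
* **Confounding**: `confound_shift` (default 20 °C in the confound
  scenario — the scale of the mesophile/thermophile difference) is added to
  the OGT of the clade whose size is closest to half the leaves, after
  evolution, while FOD evolves independently. This is the minimal
  construction in which a leaf-level OGT–FOD association is purely
  phylogenetic: naive OLS is fooled often, contrasts are not.
* **16S-like sequences**: Jukes–Cantor evolution (uniform root, per-site
  substitution probability $\tfrac34(1 - e^{-4\mu b/3})$) at
  $\mu = 0.2$/site per unit height — enough divergence that identity
  distances resolve the topology, little enough that distances stay far
  from saturation.
* **Proteomes**: per-region charge-fraction templates (sampled from region
  interiors over a polar-rich neutral background) with resampling of the
  rare draws whose finite-length composition crosses a boundary, so the
  classifier recovers the intended region for 100% of emitted sequences.
  Ortholog families copy a founder into every species with 10% point
  mutations: any two copies then share $\ge 80\%$ ungapped identity (at
  most $2 \times 10\%$ differing positions), which guarantees clustering at
  the 0.7 threshold, while unrelated founders align far below it.

What the generator does **not** emulate: realistic amino-acid substitution
processes, indels (family copies stay aligned by construction), 16S
secondary structure or rate heterogeneity, genome-scale proteome sizes, or
the biases of machine-learned disorder predictors. Passing tests therefore
demonstrate that the statistical machinery is correct under its stated
model, not that the biological conclusions of any particular real-data
study are reproduced.

## Reproducibility and problem sizes

Every generator seeds the RNG from `config$seed` plus a fixed offset per
generator, so outputs are bit-reproducible and independent of call order;
the end-to-end pipeline writes byte-identical tables across reruns with the
same seed. The validation suite uses problem sizes chosen to exercise the
asymptotics while staying desk-scale: 100 random trees of up to 16 leaves
for the ancestral-state oracle, 50 replicates of 64 leaves for slope
recovery, 1000 replicates of 32 leaves for the type-I rate, 200 replicates
for the confound comparison, 20 replicates of 8 taxa × 5000 bp for tree
recovery, 400-protein proteomes for filter enumeration, and a 16-species
pipeline for the determinism check.

## Known limitations

* The greedy clustering is exact-DP and quadratic in the number of
  clusters; it is meant for analysis-scale inputs, not millions of
  proteins.
* The bundled disorder heuristic is composition-only; window-level
  structure (e.g. alternating charge patterning) is invisible to it.
* Contrast standardization assumes the UPGMA branch lengths are meaningful
  for trait variance; when the tree is estimated from saturated or noisy
  markers, raw contrasts (also emitted) may be preferable.
* The origin-fixed regression tests association, not causation; a
  significant contrast slope still admits unmodeled correlates.
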