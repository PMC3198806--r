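---
title: "Weighted correlation networks for metabolomic profiles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted correlation networks for metabolomic profiles: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmcna)
```

## The problem

Non-targeted metabolomic profiling — for instance ^1^H-NMR concentrations of
a few dozen metabolites across tens of fruit samples — produces highly
multivariate data in which univariate testing drowns in multiple comparisons
and PCA only exposes the dominant axes of variation. Weighted correlation
network analysis addresses both: it models *all* pairwise relationships as a
weighted network, condenses the network into a handful of co-abundance
modules, and lets ordinary statistics (here one-way ANOVA) act on one
representative profile per module instead of on every metabolite.

## The pipeline, stage by stage

**Autoscaling.** Each feature is standardized to mean 0 and unit standard
deviation (sample SD, $n-1$ denominator). Metabolite concentrations span
orders of magnitude; without autoscaling, sugars and organic acids would
dominate every correlation-free analysis (PCA, SOM) simply by scale.
Pearson correlation itself is scale-invariant, so for the network the choice
is harmless; we scale once, up front, and feed the same matrix everywhere.
Zero-variance features have no defined correlation: they are set to zero,
flagged in the `constant_features` attribute, and excluded from network
construction rather than imputed.

**Adjacency.** Unsigned soft thresholding $a_{ij} = |r_{ij}|^\beta$ with
$\beta = 6$ (the conventional unsigned default). Unsigned is the right
default for ripening-type biology, where coordinated shifts produce both
strong positive and strong negative couplings that belong in the same
module; a signed variant $((1+r)/2)^\beta$ is available. $\beta$ trades
sensitivity against noise suppression; `scale_free_fit()` reports the
scale-free-topology fit across a $\beta$ sweep as a diagnostic but the
pipeline never auto-selects — a fixed, declared $\beta$ keeps runs
comparable.

**Topological overlap.** For $i \ne j$,
$$\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj},
\qquad k_i = \sum_{u \ne i} a_{iu},$$
with $\omega_{ii} = 1$. Two nodes are similar not only when directly
connected but when they share a neighborhood; this suppresses spurious
single-edge links. $\omega \in [0,1]$ whenever $a \in [0,1]$; the test
suite checks the matrix-algebra implementation against a literal triple-loop
oracle at $10^{-12}$ on random networks.

**Modules.** Average-linkage hierarchical clustering of $1-\omega$, then a
static cut. Defaults: cut height $0.95 \times$ the maximum merge height,
minimum module size 3 (sensible for a 46-feature panel; both are knobs).
The static cut is the auditable baseline; a `hybrid` option additionally
rescues pruned features into the module with which their mean topological
overlap exceeds a threshold (default 0.15), a light-weight stand-in for
dynamic tree cutting, which we deliberately do not re-implement. Modules are
renamed along the conventional color sequence by decreasing size (ties by
first-feature position); published analyses sometimes deviate from that
sequence (e.g. a third-largest module printed as "red" rather than
"brown"), so `assign_colors()` accepts a palette override.

**Eigenmetabolites and trait association.** The eigenmetabolite is the first
left singular vector of the module's samples × members submatrix of the
*autoscaled* data — consistent with the network being built on autoscaled
data — with `variance_explained` $= d_1^2 / \sum d_k^2$. SVD sign is
arbitrary, so we orient the vector to correlate non-negatively with the
module's mean profile (tie broken toward a positive largest loading); a
deterministic rule is required for reproducible plots and regression signs.
Trait association is one-way fixed-effects ANOVA at
$\alpha_{adj} = \alpha / n_\text{modules}$ (0.05/3 = 0.0167 for three
modules). The post-hoc letters use pairwise Welch t-tests at $\alpha_{adj}$
summarised by the insert-and-absorb compact-letter algorithm; Welch is our
documented choice where the convention is silent — it is robust to the
unequal group variances that arrested-ripening designs produce, and the
letter display only promises consistency with whatever pairwise test
underlies it.

**Network statistics.** Node: $k_i = \sum_{j\ne i} a_{ij}$;
$K_i = k_i/\max_j k_j$; $MAR_i = \sum a_{ij}^2 / \sum a_{ij}$;
$C_i = \sum_{j \ne i}\sum_{q \ne i,j} a_{ij}a_{jq}a_{qi} \big/ (k_i^2 - \sum_j a_{ij}^2)$,
defined as 0 when the denominator vanishes (isolated or single-edge nodes).
Module: density (mean off-diagonal adjacency), centralization
$\frac{n}{n-2}\left(\frac{\max k}{n-1} - \text{density}\right)$ (undefined
at $n=2$, reported `NA`), heterogeneity = population CV of $k$,
$\sqrt{\overline{k^2}/\bar{k}^2 - 1}$ — scale-invariant, 0 for regular
graphs. Two scope decisions were genuinely open and are parameters:

* node statistics default to the **whole-network** adjacency (`scope =
  "network"`), the reading consistent with a published hub table whose
  scaled-connectivity column is reproduced by $k_i/\max(k)$ over the whole
  network, while module statistics always use the module's induced
  submatrix;
* statistics are computed on the **adjacency**, not the TOM — connectivity
  and the maximum adjacency *ratio* are adjacency-level concepts — with the
  TOM variant available by passing the TOM matrix and labeling
  `matrix_type = "tom"`.

A related arithmetic note: recomputing a hub table's scaled connectivity
from its printed two-decimal connectivity column reproduces the printed
values except where the original authors divided unrounded numbers (1.05 /
1.66 rounds to 0.63, not the printed 0.64); the acceptance test excludes
that one row and documents why.

## Baselines

**PCA** is the SVD of the centered matrix with a deterministic sign
convention (largest-magnitude loading positive). `top_loadings()` reproduces
the usual loading-screening workflow (e.g. report features with loadings
above 0.20 or below −0.10 on a component).

**BL-SOM** maps *features* (not samples) onto a small 2-D lattice.
Batch learning: each epoch assigns every feature to its nearest reference
vector, then replaces each reference vector by the Gaussian
neighborhood-weighted mean of assigned features; the radius shrinks linearly
to zero, so late epochs are plain batch k-means on the lattice.
Initialization spans the first two principal-component axes of the feature
cloud, making the fit deterministic given the data — randomness only enters
through an optional jitter behind a seed. Defaults: ~$5\sqrt{n}$ cells in a
near-square lattice, 100 epochs, initial radius half the lattice side; the
original batch-SOM tooling never published its schedule, so ours is a
documented default, not a reproduction. `blsom_compare()` implements the
heat-map categories: per metabolite the contrast (sample vs sample, or
sample vs population mean) is divided by the population SD; a cell takes the
most extreme category among its members, with boundaries at ±1 SD
(strong/weak up/down).

## The synthetic world

`synthetic_spec()` fixes the generator to the study design it emulates:
6 genotypes × 10 fruits = 60 samples; 46 features as three co-abundance
blocks of 13, 12 and 6 plus 15 independent background features; within-block
correlation $\rho = 0.8$; genotype effects of 1.5 SD following the published
association pattern (ripeness drives blocks 1–2, genetic background
additionally block 2, block 3 high in the modern-background parents but not
their hybrid). Blocks are built from a single latent factor per block
($x = \sqrt{\rho}\,g + \sqrt{1-\rho}\,\varepsilon$), which yields exactly
$\rho$ pairwise correlation, is $O(n)$, and is positive-definite by
construction. Values are shifted by +8 SD (and floored at 0) so the output
is a valid non-negative concentration table; autoscaling removes the shift.

What the generator does **not** emulate: lognormal concentration scales and
heteroscedastic NMR noise, overlapping resonances and binning artifacts,
block-to-block correlation beyond what shared genotype effects induce, and
unequal group sizes. A green planted-recovery test therefore establishes
that the pipeline recovers clean latent-factor blocks under the declared
design — not that it would segment any real fruit metabolome the same way.
The published 13/12/6/15 partition of the real data is deliberately *not* a
test target: the exact cut parameters behind it are unstated and the raw
table is not deposited.

## Numerical choices

* Exact symmetry of correlation matrices is enforced by averaging with the
  transpose and clamping to $[-1, 1]$; downstream validators then accept a
  $10^{-8}$ asymmetry tolerance.
* Bins in `bin_spectrum()` are half-open $[b, b + w)$ and exclusion windows
  are treated half-open as well; that convention is what makes the classic
  fingerprint arithmetic exact (475 bins on $[0.5, 10)$ at 0.02 ppm minus 25
  in $[4.5, 5)$ = 450), with a $10^{-9}$-width guard against float jitter at
  aligned edges.
* Ties in SOM best-matching-unit search resolve to the lowest cell index;
  `hclust` provides deterministic agglomeration.
* The ANOVA F statistic is taken from the standard linear-model
  decomposition; degenerate groups with identical value multisets short-cut
  to $p = 1$ in the pairwise Welch step (zero variance in both groups).
* All generator randomness sits behind one seed, and the global RNG state is
  saved and restored, so library calls never perturb a caller's stream.

## Known limitations

* No dynamic-hybrid tree cut with PAM stage; the `hybrid` rescue is a
  simpler surrogate.
* Statistics are $O(n^3)$ dense-matrix computations — appropriate for
  metabolite panels (tens to hundreds of features), not for $10^4$-probe
  transcriptomes; no block-wise TOM is provided.
* Traits are categorical only; continuous-trait correlation and mixed models
  are out of scope.
* The type-I calibration test accepts the binomial 95% interval around the
  nominal adjusted threshold; mild conservatism or anti-conservatism within
  that band (e.g. from testing three correlated module eigenmetabolites per
  replicate) is not resolved further.
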