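---
title: "Longitudinal subfield structural covariance networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal subfield structural covariance networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippnet)
```

## The scientific problem

Hippocampal atrophy in neurodegeneration is not spatially uniform: the
subfields (CA1–CA4, dentate gyrus, subiculum and its neighbours, molecular
layer, fimbria, HATA, tail, fissure) lose volume at different rates, and —
critically — their losses are *correlated* across subjects. A pair of
subfields whose two-year percentage volume changes co-vary strongly after
covariate adjustment is said to co-atrophy. Treating the 38
hemisphere-specific subfields as nodes and significant co-atrophy partial
correlations as weighted edges yields a longitudinal structural covariance
network, and graph centrality then identifies subfields that are
organisational hubs of coordinated degeneration rather than merely fast
shrinkers.

`hippnet` implements that full chain plus a synthetic cohort generator, so
the statistical machinery can be exercised and validated end to end without
access-restricted participant data.

## Change scores and longitudinal tests

All change scores are per-subject percentages,
$100\,(x_{\text{follow-up}} - x_{\text{baseline}})/x_{\text{baseline}}$,
applied to subfield volumes (mm³) and to the MMSE (0–30 points). A
subfield's reported mean change is the **mean of per-subject ratios**, not
the ratio of mean volumes; the two differ when baseline volume and change
are correlated, and the per-subject convention is the one consistent with a
per-subject change formula. Paired t-tests compare raw follow-up vs
baseline volumes per subfield.

The hemispheric asymmetry contrast averages each subject's 19 left and 19
right subfield changes (unweighted — each subfield counts equally,
matching the convention of reporting a per-hemisphere average of subfield
changes; a volume-weighted variant is available via the `weights`
argument) and paired-tests left against right. Aggregate regions (whole
hippocampus, head, body) are computed from *summed volumes* before the
change computation; they are reporting conveniences and never enter the
network, whose roster is exactly the 38 subfields.

p-values are two-sided and uncorrected by default, since per-subfield and
per-edge inference at α = 0.05 is the convention this analysis follows; an
optional Benjamini–Hochberg mode exists for both the atrophy report and
the network threshold.

## Partial correlation

The association and network stages both use the partial Pearson
correlation of two variables given covariates $Z$ (baseline age, sex,
education band 0–3, APOE ε4 allele count 0/1/2): residualise both
variables on $[1, Z]$ by least squares and correlate the residuals. The
test statistic is $t = r\sqrt{df/(1-r^2)}$ with $df = n - k - 2$, $k = 4$.
Education enters as a single ordinal covariate rather than dummies — the
lowest band is typically nearly empty (a few subjects), making dummy
coding unstable — and APOE as an allele count (0/1/2), which nests the
binary carrier coding while retaining dose information. Both choices are
recodings the partial correlation is provably invariant to up to affine
transformations, which the test suite checks explicitly.

Implementation detail: all 38 change columns are residualised in one QR
pass and correlated as a matrix, so the pairwise matrix is exactly
symmetric and bit-consistent with looped single-pair calls (a tested
invariant). Degenerate inputs (rank-deficient designs, zero-variance
residuals) are errors naming the offending pair, never silent p = 0.

## Network construction

Edges are retained where the pairwise partial-correlation p-value is below
α (default 0.05, per-edge, uncorrected); the retained edge weight is the
**signed** partial correlation, and binarisation (for degree, and for
shortest paths in binary mode) treats any nonzero weight as an edge.
Negative-weight edges are kept by default — nothing in the thresholding
rule excludes them — with a `positive_only` flag to restrict. Edge sets
are monotone in α, self-loops are structurally excluded (the diagonal is
forced to zero), and the maximum possible degree is therefore N − 1 = 37.
A reported degree of 38 in a 38-node simple graph would imply
self-correlation counted as an edge; the package deliberately does not
emulate that.

## Centrality metrics

* **Degree** $D_i = \sum_j a_{ij}$ on the binarized graph.
* **Betweenness** $B_i = \sum_{x<y} g_{xiy}/g_{xy}$, unnormalized,
  endpoints excluded, unordered pairs counted once, tied geodesics counted
  fractionally. Computed by Brandes' dependency accumulation; pairs with
  no connecting path contribute zero.
* **Closeness** $C_i = (N-1)/\sum_j l_{ij}$ on connected graphs. On
  disconnected graphs the Wasserman–Faust convention is used:
  $C_i = \frac{R_i}{N-1}\cdot\frac{R_i}{\sum_{j \text{ reachable}} l_{ij}}$
  with $R_i$ the reachable count; isolated nodes score zero.
* **Eigenvector** centrality is the principal eigenvector of the
  (binarized or absolute-weight) adjacency matrix, L1-normalized so
  components sum to one, with λ the largest adjacency eigenvalue.

In weighted mode the shortest-path length of an edge is $1/|r|$ (stronger
co-atrophy = shorter path) and eigenvector centrality uses $|a_{ij}|$,
keeping the matrix non-negative so the Perron eigenvector is non-negative.
Binary mode is the default: the degree definition is explicitly binary,
and the betweenness/closeness formulas are stated in unweighted form; the
profile records the mode used.

### Numerical choices

The power iteration runs on $A + I$: a unit diagonal shift that preserves
eigenvectors but maps eigenvalues $\mu \mapsto \mu + 1$, so the principal
eigenvalue strictly dominates in magnitude even on bipartite graphs
(where plain iteration on $A$ oscillates between the $\pm\lambda$
eigenvectors — a path graph is the simplest failure case). The start is
the deterministic uniform vector $1/N$; convergence is declared at
relative change $10^{-12}$, a cap of $10^5$ iterations errors out with
the achieved residual, and λ is the Rayleigh quotient on the unshifted
matrix. On disconnected graphs the result is dominated by the
largest-eigenvalue component (components in eigenvalue ties split the
mass); a warning lists the component sizes. Weighted shortest-path
tie detection uses a relative tolerance of $10^{-12}$ on path lengths.

### Consensus hubs

Per metric, nodes are ranked by descending value with ties broken by
canonical roster order; the consensus set is the intersection of the four
top-k sets (k = 5 by default). Boundary ties (the k-th value equal to the
(k+1)-th) are flagged per metric, since under symmetry (e.g. a complete
graph, where betweenness is identically zero) top-k membership is decided
purely by the tie-break and should be read as such.

## The synthetic cohort generator

`simulate_cohort()` draws from a latent-factor model: subject $i$'s change
in subfield $j$ is
$\mu_j + (Lf_i)_j + \varepsilon_{ij}$ with $f_i \sim N(0, I)$ and
$\varepsilon_{ij} \sim N(0, \sigma^2)$. The defaults are fixed study-scale
conditions, not tuning knobs:

* n = 258; age 75.1 (7.17) y; 39.53 % female; APOE ε4 allele counts
  2/1/0 with probabilities 0.1589/0.4768/0.3643; education bands
  0.0155/0.1318/0.4651/0.3876.
* MMSE baseline 26.40 (1.93); latent percentage decline mean −12.9,
  SD 13.8, coupled to the first (global) latent factor with weight 5 so
  that greater atrophy accompanies greater decline (positive
  atrophy–cognition correlations of roughly 0.2–0.25, the magnitude
  typical of subfield–MMSE associations at this scale).
* Atrophy means: the five largest published subfield decreases are pinned
  (left fimbria −9.11 %, left presubiculum head −7.99 %, left subiculum
  head −7.93 %, right CA3 body −7.07 %, left CA3 body −7.03 %); the
  remaining subfields follow a structure-level severity profile shifted so
  hemispheric means are exactly −6.35 % (left) and −5.47 % (right).
* Loadings: a global factor (2.5), one factor per hemisphere (1.5), and a
  CA/dentate block factor (2.0), with idiosyncratic noise SD 1.5 —
  giving strong, anatomically structured co-atrophy blocks (within-block
  correlations around 0.8–0.9).
* Baseline volumes are log-normal (means at FreeSurfer-plausible values,
  sdlog 0.15) — positivity is guaranteed; per-subfield baseline means are
  not published for the reference cohort, so these are order-of-magnitude
  defaults and fully overridable.

MMSE scores are integers clipped to [0, 30]. This matters for validation:
the *observed* decline percentage (recomputed from integer scores)
carries rounding noise and a ceiling truncation at 30, which shrink its SD
to about 13.2 against the latent 13.8 and shift the mean slightly. The
generator-validation checks therefore measure the latent decline (exposed
as `latent_decline_pct`), which is the quantity the configuration
parametrises; the observed/latent gap is a deliberate feature of emulating
a coarse integer instrument.

What the generator does **not** emulate: segmentation error and
scanner/site effects, missing visits and attrition, non-Gaussian change
distributions, age- or sex-dependent atrophy rates, and any spatial
autocorrelation beyond the specified factor blocks. Tests passing on this
generator validate the statistical machinery — estimators, thresholding,
graph algorithms — not claims about real cohorts.

`planted_hub_config()` supports hub-recovery validation: a single factor
loading 6 on one subfield and 0.4 on all others with noise SD 1.5 gives
hub–spoke population correlations near 0.25 (per-edge detection power
≈ 0.98 at n = 258, α = 0.05) and spoke–spoke correlations near 0.066
(retention ≈ 0.18), i.e. a star-dominated significance graph in which the
planted subfield should lead all four metrics. These values were chosen by
this power calculation, before any recovery experiment.

With the *default* config, by contrast, every pairwise partial correlation
exceeds 0.4 and the α = 0.05 network is complete: degree saturates at 37,
betweenness is identically zero, and the consensus set is decided by
tie-breaks — the generator reproduces the near-saturated degree tables
characteristic of strongly coupled co-atrophy, which is why hub-recovery
validation uses the planted configuration instead.

## Validation strategy and problem sizes

The test suite validates every stage against independent oracles at sizes
chosen to keep the full run inside a few minutes on one CPU:

* centrality vs brute force (matrix-power distances and geodesic counts,
  dense eigendecomposition) on 500 random graphs of up to 8 nodes,
  including disconnected ones, to 1e-8; igraph as an additional
  cross-check on connected graphs (binary and weighted modes);
* partial correlation: QR-residualisation route vs the
  inverse-correlation-matrix identity on 1000 random (n = 50, k = 4)
  instances, to 1e-10;
* type-I error: 200 null cohorts (independent changes, n = 258) — the
  fraction of retained edges and of flagged associations at α = 0.05 must
  lie within the 99 % binomial band around 0.05;
* hub recovery: 100 planted-hub cohorts at n = 258, requiring ≥ 95 %
  consensus-top-5 recovery;
* generator moments at n = 20 000, within 3 standard errors of the
  configured targets;
* full-pipeline determinism: two runs with the same seed must be
  byte-identical.

## Known limitations

* The pipeline consumes volume tables; it has no knowledge of images or
  segmentation quality.
* Network inference is marginal per edge (significance thresholding), not
  a joint sparse-precision estimate; no bootstrap edge-stability analysis
  is provided.
* Centrality on near-complete graphs is mostly tie-break; interpret the
  consensus set together with the reported tie flags.
* Partial Spearman correlations and longitudinal mixed models are out of
  scope.
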