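# hippnet

Network-based analysis of longitudinal hippocampal subfield atrophy.

`hippnet` is for neuroimaging researchers who have per-subject baseline and
follow-up volumes of the 38 FreeSurfer hippocampal subfields (19 per
hemisphere: CA1/CA3/CA4, dentate gyrus, molecular layer, subiculum and
presubiculum split into head and body, plus parasubiculum, fimbria, HATA,
hippocampal tail and hippocampal fissure) together with cognitive scores and
demographic covariates, and who want to study *coordinated* atrophy rather
than region-by-region change. The package implements the full chain:

1. **Change scores.** For every subfield and subject,
   `change% = 100 (V_followup − V_baseline) / V_baseline`, and likewise
   `decline% = 100 (MMSE_followup − MMSE_baseline) / MMSE_baseline`.
2. **Longitudinal tests.** Paired t-tests of follow-up vs baseline volumes
   per subfield, and a paired test of per-subject left- vs right-hemisphere
   mean change (hemispheric asymmetry).
3. **Atrophy–cognition association.** Partial Pearson correlations between
   each subfield's change and MMSE decline, adjusting for baseline age,
   sex, education band and APOE ε4 allele count
   (`df = n − k − 2`, k = 4).
4. **Structural covariance network.** Pairwise covariate-adjusted partial
   correlations between all subfield change vectors; edges with p < α
   (default 0.05) keep their signed correlation as weight, all others are
   set to zero — an undirected, weighted co-atrophy graph.
5. **Centrality and hubs.** Four node metrics:
   degree `D_i = Σ_j a_ij` on the binarized graph; unnormalized betweenness
   `B_i = Σ_{x<y} g_xiy / g_xy` (fractional counting of tied geodesics);
   closeness `C_i = (N−1)/Σ_j l_ij` (Wasserman–Faust corrected on
   disconnected graphs); eigenvector centrality `E = A E / λ`,
   L1-normalized, with λ the largest adjacency eigenvalue. A *consensus
   hub* is a subfield ranked in the top k (default 5) for all four metrics
   simultaneously.

Because participant-level cohort data of this kind are access-restricted,
the package ships a seeded synthetic cohort generator
(`simulate_cohort()`) whose defaults emulate a reference cohort of 258
MCI-to-AD progressors (age 75.1 ± 7.17 y, 39.5 % female, MMSE
26.4 ± 1.93 declining 12.9 % over two years, per-subfield atrophy −5 to
−9 % with left > right asymmetry) with latent-factor co-atrophy structure.
Every stage is validated against independent brute-force oracles on this
generator.

## Worked example

```r
library(hippnet)

cohort  <- simulate_cohort(default_cohort_config(seed = 1))
changes <- compute_change_table(cohort)

hemispheric_asymmetry(changes)
#> # A tibble: 1 × 7
#>   left_mean_pct right_mean_pct mean_diff t_stat       p_value     n    df
#>           <dbl>          <dbl>     <dbl>  <dbl>         <dbl> <int> <int>
#> 1         -6.49          -5.65    -0.843  -6.06 0.00000000481   258   257
```

The left hemisphere lost 6.49 % of subfield volume on average against
5.65 % on the right; the paired test across 258 subjects says this
asymmetry is far beyond chance (p ≈ 5 × 10⁻⁹).

```r
net  <- changes |>
  pairwise_partial_correlations(cohort_covariates(cohort)) |>
  threshold_network(alpha = 0.05)
net
#> <hippnet_network> 38 nodes, 703 edges (alpha = 0.05)

prof <- centrality_profile(net)
consensus_hubs(prof, k = 5)
```

With the default generator's strong global co-atrophy factor every pairwise
partial correlation is significant at n = 258, so the network is complete
(703 edges) — mirroring the near-saturated degrees seen in real co-atrophy
tables. Sparser, hub-dominated structures (e.g.
`planted_hub_config()`) produce informative betweenness and a non-trivial
consensus set.

`run_pipeline()` chains all stages and writes every artifact (change table,
atrophy report, asymmetry, associations, r/p matrices, adjacency, edge
list, centrality table, hub report, manifest) to a directory,
byte-reproducibly for a fixed seed. `autoplot()` methods cover the
correlation heatmap and centrality profiles; `tidy()`/`glance()` give
broom-style summaries.

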