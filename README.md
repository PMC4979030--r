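# clustercorr

Correlation-based cluster quantification — and its biases — for spatial point
patterns, as used in single-molecule localization microscopy (PALM/STORM)
cluster analysis.

Protein clusters imaged by SMLM are routinely characterized with two
"model-free" estimators built on second-order spatial statistics:

1. the **radius of maximal aggregation** `r_a`, the location of the maximum of
   Besag's `L(r) − r = sqrt(K(r)/π) − r`, used as a cluster-size proxy;
2. the **exponential pair-correlation approximation** of PC-PALM,
   `g_a(r) = 1 + a·exp(−r/d)`, whose fitted amplitude `a`, correlation length
   `d` and implied occupancy `N_a = 2π a d² ρ` serve as ensemble cluster
   parameters.

Both are biased in ways that depend on the (unknown) cluster-generating
process. `clustercorr` makes those biases computable. For Neyman–Scott
cluster processes — Poisson parents of intensity `κ`, offspring displaced by a
radially symmetric kernel with size parameter `r_t` — the K-function takes the
canonical form

    K(r) = π r² + H_d(r) / κ            (Poisson offspring counts)

with `H_d` the CDF of the intra-cluster pair distance. The package provides,
for the Gaussian (Thomas), disk (Matérn), Cauchy and variance-Gamma kernels
and an Ornstein–Zernike Ising form:

- **Closed-form theory**: `H_d`, `h_d`, `K`, `L(r) − r`, `g(r)`, the quadratic
  monomer-background law `B_e = B β²`, offspring radial quantiles and the
  occupancy integral `N = ρ ∫ (g − 1) 2π r dr`.
- **Bias of `r_a`**: the stationarity condition `K′(r_a)² = 4π K(r_a)`
  rearranges to `A = h(r_a)² / (4π (H(r_a) − r_a h(r_a)))`, so
  `p = r_a / r_t` depends nonlinearly on `κ r_t²` and is bounded below by the
  root of `H_d(r) = r h_d(r)` — a model constant (disk: **1.29564** with
  `p < 2`; Gaussian: **2.24181** with no upper bound). `solve_ra()`,
  `p_lower_bound()`, `bias_map()`.
- **Normalized K**: the variance-normalized statistic
  `(K(r) − π r²)/c(r, n, A, P)`; its maximizer converges at large windows to
  the `L`-based lower bound (≈ 1.296·R for disks) but depends on the point
  count `n` in smaller windows. `normalized_K()`, `normalized_ra()`.
- **Scaling laws of the exponential fit**: least-squares fitting of `g_a` to
  each family's true PCF gives constant ratios `m = d/r_t`, `n = a/a_t`,
  `l = N_a/N_t` (Gaussian: 1.54, 1.26, 1.49 — occupancy overestimated by
  ~50%; variance-Gamma: exactly 1, 1, 1; Ising: `m = 0.5`, `l = 0.58`,
  occupancy underestimated by ~40%). `fit_exponential_lse()`,
  `scaling_laws()`, `ising_amplitude_ratio()`.
- **Monte-Carlo machinery**: a seedable Neyman–Scott simulator with CSR
  background, translation-corrected empirical `K`/`L`/`g` estimators,
  minimum-contrast model fitting, and reproducible validation studies
  (`study_ra_recovery()`, `study_cluster_count_recovery()`).

## Worked example

```r
library(clustercorr)

# a Thomas process: 25 clusters per unit area, sigma = 20 nm in um units
m <- cluster_model("gaussian", r_t = 0.02, kappa = 25, mu = 40)
solve_ra(m, q = 0.95)
#> radius of maximal aggregation: r_a = 0.0560408, p = r_a/r_t = 2.80204 (bounds 2.24181 .. Inf)
#>   p_0.95 = 1.14474

pp <- simulate_neyman_scott(m, cc_window(1), seed = 7)
estimate_cluster_report(pp, estimator_config(n_bins = 256), family = "gaussian")
#> cluster report: 1507 points, intensity 1507
#>   exponential fit: a = 7.374, d = 0.0261  ->  N_a = 47.57
#>   gaussian-corrected: r_t = 0.017, N = 32.01
#>   minimum contrast [gaussian]: kappa = 42.86, r_t = 0.01829, N = 35.16
```

Reading: the maximum of `L(r) − r` sits at 2.8 times the true `σ` — and the
theory says that for *any* Thomas parameters it sits at least 2.24 σ away, so
`r_a` is not the cluster radius. The exponential-fit occupancy `N_a = 47.6`
overestimates the true `μ = 40` (theoretical factor `l ≈ 1.49` on replicate
average); dividing by the Gaussian scaling laws corrects it back. The
single-replicate scatter visible here (corrected `N = 32`) averages out over
replicates — `study_cluster_count_recovery()` reproduces the `l` factor and
the near-unbiasedness of the model-PCF route.

```r
scaling_table()
#>     family         m        n         l        m_q    q
#> 1 gaussian 1.5357832 1.260115 1.4860727 0.62742731 0.95
#> 2     disk 0.8049878 1.808271 1.4919425 0.82590002 0.95
#> 3   cauchy 1.6924029 1.175974 0.8420646 0.08472612 0.95
#> 4 vargamma 1.0000000 1.000000 1.0000000 0.28191888 0.95
#> 5    ising 0.4999381       NA 0.5848117         NA 0.95
```

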