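# shadegrass

Detecting **environmental (light) filtering** and **biotic interactions**
in mapped, twice-censused plant communities along an experimental light
gradient.

The package is aimed at community ecologists analysing blocked shading
experiments: plots that regenerate from a shared seed bank under different
shading treatments, with every individual identified to species and mapped,
at an initial census (t1) and a final census (t2). Two complementary
statistics carry the inference:

- **Change in compositional dissimilarity.** For communities *j*, *k*,
  ΔB<sub>j,k</sub> = B<sub>j,k</sub><sup>t2</sup> − B<sub>j,k</sub><sup>t1</sup>,
  where B is the Bray–Curtis dissimilarity Σᵢ|xᵢ − yᵢ| / Σᵢ(xᵢ + yᵢ) over
  species abundances. Light filtering predicts that communities under
  *different* light regimes diverge (ΔB > 0) more than communities under
  the *same* regime, and that divergence grows with the illumination
  difference. The package provides one- and two-sample Student's t tests of
  ΔB (with a Welch option and a block-restricted permutation test as
  robustness checks) and the OLS regression of ΔB on illumination
  difference with its 95% pointwise confidence band.
- **Change in relative neighbourhood density.** Per plot, the pair
  correlation function g(r) — the density of further individuals at
  distance r from a typical individual, standardised by the squared mean
  intensity — is estimated with an Epanechnikov-kernel estimator using
  Ripley's isotropic edge correction on the rectangular window, and
  Δpcf(r) = pcf<sub>t2</sub>(r) − pcf<sub>t1</sub>(r) is averaged across
  the replicate plots of each treatment with a 95% t confidence band
  (a mean ± 1 SD band is also available). Where the whole band falls below
  zero the loss of close neighbours is read as competition; wholly above
  zero as facilitation.

Because such field data sets are rarely deposited, the package ships a
fully seeded synthetic-experiment generator (`generate_experiment()`) that
emulates the design: 12 blocks × 4 shading treatments (strong shade at
10 mol·m⁻²·d⁻¹), 48 plots of 1.1 × 0.9 m drawing ~986 individuals each
from a shared 39-species seed bank, followed by light-dependent
(Gaussian light-niche) and crowding-dependent mortality. Every analysis
stage is therefore testable end to end, including parameter recovery.

## Worked example

```r
library(shadegrass)

exp <- generate_experiment(sim_config(seed = 42))
exp
#> <grass_experiment> 75899 individuals | 48 plot(s) | censuses: t1, t2 | window 1.1 x 0.9 m

pairs <- delta_dissimilarity(exp, level = "plots")
delta_b_tests(pairs)
#> # A tibble: 3 × 7
#>   test               group              n mean_delta_B statistic    df   p_value
#>   <chr>              <chr>          <int>        <dbl>     <dbl> <dbl>     <dbl>
#> 1 one_sample_vs_zero different_tre…   864       0.152       56.2   863 9.67e-291
#> 2 one_sample_vs_zero same_treatment   264       0.0282      24.8   263 8.23e- 71
#> 3 two_sample_pooled  different_vs_…  1128       0.124       25.1  1126 1.10e-110

regress_delta_on_light(pairs)
#> <grass_lightreg> slope = 0.00975 per mol m^-2 d^-1, R^2 = 0.840, p = 0, n = 864
```

Read: between-treatment pairs diverged much more (mean ΔB = 0.152 over 864
pairs) than same-treatment pairs (0.028 over 264 pairs); the pooled
two-sample t confirms the contrast, and divergence grows by ~0.0098 ΔB per
mol·m⁻²·d⁻¹ of illumination difference — the light-filtering signature.
(Under this generator seed filtering is strong, so the test statistics are
far larger than any field study would show.)

```r
calls <- delta_pcf_summary(exp)
dplyr::count(calls, treatment, classification)
#> # A tibble: 10 × 3
#>    treatment classification     n
#>    <chr>     <chr>          <int>
#>  1 low       negative          14
#>  2 low       none              85
#>  3 low       positive           2
#>  4 moderate  negative          11
#>  5 moderate  none              90
#>  6 no        negative           8
#>  7 no        none              92
#>  8 strong    negative           9
#>  9 strong    none              92
#> ...
```

Counts are r-grid points per treatment whose replicate band lies wholly
below ("negative") or above ("positive") zero. The default dynamics apply
mild crowding mortality, so a minority of small-r points are called
negative. `plot_delta_pcf(calls)`, `plot_light_regression(pairs)` and
`plot_delta_b_groups(pairs)` draw the corresponding figures, and
`run_analysis()` / `write_report()` produce all tables plus a JSON run
manifest in one call.

Field data are read from CSV with
`read_census("census.csv")` (columns
`plot_id,block_id,treatment,census,species_id,x,y`, metres, censuses `t1`
and `t2`, plus an optional JSON sidecar carrying the window and the
treatment → illumination map).

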