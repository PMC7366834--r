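---
title: "Methods: delta-B and delta-pcf analysis of mapped shading experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-B and delta-pcf analysis of mapped shading experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`shadegrass` analyses mapped, twice-censused plant communities arranged in
a randomized-block light-gradient experiment. This vignette is the
package's account of the two inferential procedures it implements, of the
synthetic-data generator that stands in for field data, and of the
numerical and design choices a user should know about.

## The inference problem

Two assembly processes leave distinguishable fingerprints in such an
experiment:

* **Environmental (light) filtering** removes species that cannot tolerate
  the local light regime. Communities germinating from one shared seed
  bank should therefore *converge* in composition under the same shading
  treatment and *diverge* under different treatments, the more so the
  larger the illumination contrast.
* **Biotic interactions** between established neighbours act at short
  distances. Competition removes close neighbours and lowers the relative
  neighbourhood density at small spatial scales; facilitation raises it.

The package separates the two signals with a compositional statistic
(delta-B) and a spatial one (delta-pcf).

## Delta-B: change in compositional dissimilarity

For communities $j,k$ with abundance vectors $x, y$, the Bray–Curtis
dissimilarity is $B_{j,k} = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, and

$$\Delta B_{j,k} = B^{t2}_{j,k} - B^{t1}_{j,k}.$$

`delta_dissimilarity()` computes one record per unordered plot pair
(grouped into same-treatment and different-treatment pairs, with the pair's
illumination difference attached) and, at `level = "subplots"`, per
within-plot subplot pair. Pairs in which any community is empty at either
census are excluded and counted: Bray–Curtis against an all-zero vector is
undefined, and imputing it would manufacture signal. Abundances enter as
raw counts with no standardisation or transformation.

Inference follows the classical design: one-sample Student's t tests of
$\Delta B$ against zero per group, a pooled-variance two-sample t test for
the different- vs same-treatment contrast, and an OLS regression of
$\Delta B$ on illumination difference with its 95% pointwise confidence
band. Two caveats are built into the interface rather than hidden:

* Pairwise $\Delta B$ values are not independent — with 48 plots each plot
  enters 47 pairs. The plain t tests reproduce the standard field
  procedure; `delta_b_permutation()` additionally permutes treatment
  labels *within blocks* and recomputes the two-sample statistic, giving a
  design-respecting p-value. The two results are reported separately.
* "Student's t test" is taken at its word: the two-sample test pools
  variances by default, with Welch available via `var_equal = FALSE`.
  P-values are two-sided throughout.

The regression defaults to using every between-treatment pair as a point;
`aggregate = "treatment_pairs"` first averages within each unordered
treatment pair, for users who prefer one point per light contrast.

## Delta-pcf: change in relative neighbourhood density

Per plot and census, the pair correlation function is estimated on the
rectangular window $W$ by the kernel sum

$$\hat g(r) = \frac{1}{2\pi r \, \hat\lambda^2 |W|}
  \sum_{i \ne j} e_i(d_{ij})\, \kappa_h(r - d_{ij}),$$

with Epanechnikov kernel $\kappa_h$, Ripley isotropic edge weights $e_i$
(the reciprocal fraction of the circle of radius $d_{ij}$ around point $i$
lying inside $W$, in closed form for the rectangle and verified against
numeric arc integration), and the unbiased pair-intensity estimate
$\hat\lambda^2 = n(n-1)/|W|^2$ (the naive $n^2/|W|^2$ is switchable). The
estimator is species-blind: it describes the whole community's spatial
structure. Under complete spatial randomness $g \equiv 1$.

$\Delta\mathrm{pcf}(r) = \mathrm{pcf}_{t2}(r) - \mathrm{pcf}_{t1}(r)$ is
computed per plot on a shared distance grid with a single shared bandwidth,
then averaged across the replicate plots of each treatment
(`delta_pcf_summary()`). The replicate band is the 95% t interval
(mean ± $t_{0.975,\,n-1}$·SE) by default; a mean ± 1 SD band is available
via `band_type` because both conventions circulate for this kind of figure,
and they are not interchangeable — the band type is always recorded in the
output. The classification rule is strict and pointwise: "negative"
(competition) where the whole band is below zero, "positive"
(facilitation) where wholly above, "none" otherwise. Widening a band can
therefore only move calls toward "none".

### Numerical choices

* **Bandwidth.** Stoyan's rule of thumb $h = 0.15/\sqrt{\hat\lambda}$, the
  de-facto standard for kernel pcf estimation. For delta-pcf one bandwidth
  is computed from the pooled density of both censuses (experiment-wide,
  so replicate curves share a grid) — otherwise the density drop between
  censuses would change the smoothing and masquerade as a spatial signal.
* **Distance grid.** 101 points from $h$ to $\min(\text{width},
  \text{height})/4$ (0.225 m for the default window). Below the bandwidth
  the $1/r$ factor makes the estimator unstable, so it is not evaluated
  there.
* **Edge weights.** Closed-form rectangle solution handling interior,
  edge and corner cases; weights are capped at 4 (the corner maximum for
  small radii), and pairs farther apart than half the window diagonal —
  beyond the closed form's validity — are excluded from the sum.
* **Empty or near-empty plots.** Plots with fewer than 2 individuals at
  either census are excluded from delta-pcf with a message; emptied plots
  are retained in the experiment and flagged, never silently dropped.

### A known small-sample property

Density-*dependent* mortality (the competition regime itself) correlates
survival events through the shared neighbourhood field, which
over-disperses the survivor count $n_{t2}$. Because $\hat g$ normalises by
the plot's own $n_{t2}(n_{t2}-1)$, very strong crowding mortality shifts
the whole $\mathrm{pcf}_{t2}$ curve down by a percent or two at *all*
distances — a property of the standard estimator, not of this
implementation. At realistic mortality (the ~40% census decline the
defaults are calibrated to) the shift is well inside the replicate band;
users simulating extreme mortality regimes should expect occasional
far-field "negative" calls from this mechanism and read small-scale
structure against the far-field baseline.

## The synthetic-experiment generator

`generate_experiment()` emulates the field design so the full pipeline can
be exercised and validated without field data:

* **Layout.** 12 blocks, each holding one 1.1 × 0.9 m plot per shading
  treatment (48 plots). The strong-shade illumination is 10 mol·m⁻²·d⁻¹ —
  a measured understory value; the experiment's lighter treatments have no
  published illuminations, so the defaults 40/30/20 mol·m⁻²·d⁻¹ are an
  assumed evenly spaced gradient, configurable via `light_map` and flagged
  as an assumption, not data.
* **Seed bank.** One shared species pool (default 39 species, lognormal
  rank-abundance, $\sigma_{\log} = 1$); every plot draws its species
  labels i.i.d. from the same proportions — the shared-seed-bank
  assumption that underpins the convergence prediction. Each species has a
  Gaussian light niche: optimum $\mu_s$ uniform over the illumination
  range, tolerance $\sigma_s$ uniform on 12–24 mol·m⁻²·d⁻¹.
* **Initial census.** Per-plot counts Poisson($\lambda_0 |W|$) with
  $\lambda_0 = 47322/48/|W| \approx 996$ individuals·m⁻² (the field
  experiment's initial density); positions CSR by default, or a Thomas
  cluster process (uniform parents, Gaussian offsets, out-of-window
  offspring rejected and redrawn) for clumped germination.
* **Dynamics.** One composite Bernoulli survival step:
  $p = \min\{1,\; p_0 \, F^{\varphi} \, e^{-c\,n_r}\}$ with light match
  $F = \exp(-(L - \mu_s)^2 / 2\sigma_s^2)$, $n_r$ the number of t1
  neighbours within $r_c$ (crowding is evaluated on the t1 configuration
  so survival events are conditionally independent — a simultaneous-update
  scheme would be untestable), and $c < 0$ giving facilitation. Only two
  censuses exist, so anything finer than one composite step would be
  unidentifiable. Defaults $p_0 = 0.90$, $\varphi = 1$, $c = 0.015$,
  $r_c = 0.05$ m are calibrated once so the expected total decline matches
  the observed censuses (47,322 → 28,037, survival 0.59); the default run
  in the README reproduces those totals to within Poisson noise.
* **Recruitment.** Off by default: the field species count rose between
  censuses (39 → 45), implying recruitment, but no mechanism is reported.
  `recruitment_rate` adds Poisson recruits drawn from the seed bank with
  uniform positions; a rate of $1 - p$ exactly restores the expected t1
  density after survival $p$, which is also what makes the package's null
  calibration exact (below).
* **Determinism.** One root seed; every stage (pool, initial census,
  dynamics) derives its own stream, so identical configs give
  byte-identical census files.

What the generator deliberately does **not** emulate: spectral light
composition (only intensity enters), soil moisture/nutrient covariates,
plant size structure and growth, multi-year dynamics, and dispersal
limitation. Passing tests on generator output therefore demonstrate that
the *statistical machinery* recovers filtering and interaction signals
under the design's assumptions — not that those assumptions hold in any
particular field system.

## Validation strategy and problem sizes

The test suite validates each layer against independent oracles: hand
formulas for Bray–Curtis, diversity indices, t and OLS statistics (to
1e-10); numeric arc integration for the edge weights (to 1e-5 over a
lattice of positions × radii); CSR theory for the pcf estimator (mean
$\hat g$ within ±0.05 of 1 over 100 plots of ~300 points); thinning
invariance and hard-core/cluster properties for delta-pcf; and pooled
recovery runs in which filtering ($\varphi = 2$) must produce the
between- vs same-treatment contrast and a positive light slope, and
crowding ($c$ set from the observed census decline) must produce negative
small-scale calls and a quiet far field. The null calibration uses 1,000
replicates of 32 reduced plots (16 disjoint, hence independent, plot
pairs of ~150 individuals each) with survival 0.6 and recruitment 0.4, so
the two censuses are exchangeable and the one-sample t test's size can be
measured against its nominal 5%. These sizes keep the whole suite at a
few minutes on a laptop while leaving every stochastic check with clear
margins.

## Known limitations

* The pairwise t tests inherit the non-independence of pairs sharing a
  plot; the permutation test is the more defensible inference and is
  reported alongside, never merged.
* The half-open subplot cells (closed on the plot's maximum edges) make
  subplot assignment unambiguous, but any individual mapped exactly on an
  interior boundary belongs to the higher cell by convention.
* The published subplot dimensions for this design (0.367 × 0.3 m, six
  per plot) do not tile a 1.1 × 0.9 m plot; the package defaults to the
  3 × 2 grid that does (0.367 × 0.45 m) and leaves the grid configurable
  rather than guessing the original intent.
* Detection, not estimation: the pipeline tests for filtering and
  interaction signatures; it does not fit $\varphi$ or $c$ to data by
  likelihood.
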