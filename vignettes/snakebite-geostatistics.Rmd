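---
title: "Methods: survey-based estimation and geostatistical mapping of snakebite incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-based estimation and geostatistical mapping of snakebite incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snakerisk)
```

This vignette is the package's account of its statistical methods: the
models, their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical decisions that were
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The problem

A national community survey samples clusters (in Sri Lanka: Grama
Niladhari divisions, the smallest administrative unit) within strata
(provinces), records the population screened in each cluster and the
number of snakebites and significant envenomings in the preceding year,
and attaches cluster-level covariates (elevation, population density,
share of agricultural workers, climatic zone). Two deliverables follow:

1. design-based provincial and national incidence rates with confidence
   intervals honouring the clustering, and
2. a continuous risk map, including exceedance-probability ("probability
   contour") maps against policy thresholds.

## 2. Design-based estimation

Within a stratum the rate is the ratio estimate
$R_h = \sum_i y_{hi} / \sum_i n_{hi}$ (reported per 100 000 person-years).
Its variance uses Taylor linearization with first-stage clusters treated
as sampled *with replacement*: with $z_{hi} = y_{hi} - R_h n_{hi}$,
$\widehat{var}(R_h) = \frac{m_h}{m_h - 1} \sum_i z_{hi}^2 / (\sum_i n_{hi})^2$.
No finite-population correction is applied — the survey this design
emulates sampled about 1% of the country's clusters, and the dominant
variation is within-cluster event randomness rather than cluster-frame
exhaustion. National rates combine strata by census population weight,
with variance $\sum_h W_h^2 \widehat{var}(R_h)$; confidence intervals are
normal-based and truncated at zero (the published intervals are
symmetric), and extrapolated counts are rounded half-up because the
reference tables print integers.

**Known limitation.** The published survey does not print its per-province
sampled denominators or exact weighting, so the estimator here is a
declared interpretation of "taking into account the cluster sampling";
national totals are reproduced from the published table rather than from
microdata.

## 3. Exploratory covariate model

Cluster counts are modelled by a Poisson GLM with offset
$\log n_i$, so coefficients live on the log incidence (per person-year)
scale. Non-linear covariate effects enter as *hinge* terms
$\max(0, x - k)$: continuous piecewise-linear slopes with a breakpoint at
$k$. Instead of smooth-curve (GAM) exploration, whose internals the
source analysis does not specify, breakpoints are chosen by a transparent
deviance scan: the knot grid is every 5 m for elevation and every 0.01
for the agricultural-worker proportion, and the selected knot is the
deviance minimiser, with the full profile returned and a flag when the
optimum is a grid endpoint (no interior slope change supported). The
published knots — 160 m (bites), 195 m (envenoming), 9% agricultural
share — are recoverable targets of this scan on simulated data.

Two scale conventions are fixed once: the agricultural share is a
proportion in $[0, 1]$ (the published "9%" is 0.09), and the dry climate
zone is the reference category. Structurally empty design columns (a
hinge with its knot at the data maximum, a dummy for an absent zone) are
aliased out rather than treated as rank deficiency, so the hinge model
with a boundary knot reproduces the plain linear fit exactly; genuine
collinearity among informative columns remains an error.

Pearson residuals $(y_i - \hat\mu_i)/\sqrt{\hat\mu_i}$ at cluster
locations feed the empirical semivariogram (half squared differences
binned by distance, half-open bins), which motivates the spatial model.

## 4. Geostatistical model and MCML

The count model is
$Y_i \mid S, Z \sim \mathrm{Poisson}(n_i \exp(d_i^\top\beta + S_i + Z_i))$
with $S$ a zero-mean Gaussian process with exponential covariance
$\sigma^2 e^{-u/\phi}$ (Matérn smoothness fixed at $\kappa = 1/2$, as
published) and $Z_i \sim N(0, \tau^2)$ iid (the nugget: cluster-level
extra-Poisson variation on the log scale). The source analysis does not
print its likelihood; this is the standard model-based-geostatistics
count formulation consistent with the published coefficient table, and
all distances are Euclidean kilometres under an equirectangular
projection declared at the domain mid-latitude, so $\phi$ is in km. (The
published $\phi = 0.091$ carries no stated unit; this package simply
declares its own.)

**Fitting.** The marginal likelihood integrates out $T = S + Z \sim
N(0, \sigma^2 R(\phi) + \tau^2 I)$ and is intractable; Monte Carlo
maximum likelihood replaces $\ell(\theta) - \ell(\theta_0)$ by the log of
an importance-sampling average over MCMC draws of $T \mid y; \theta_0$.
The sampler is a preconditioned Langevin (MALA) walk: a Newton search
finds the posterior mode, the Hessian there preconditions drift and
noise, and the step size adapts to a 57% acceptance target during
burn-in. Defaults: 2000 burn-in, thinning 8, 1000 retained draws, at most
10 re-anchorings, relative tolerance $10^{-2}$ — all overridable via
`mcml_control()`; tests run smaller, documented configurations to fit
their compute budgets.

Three numerical decisions matter and were genuinely open:

* **Trust region.** With hundreds of latent dimensions the importance
  weights degenerate rapidly as $\theta$ moves away from the anchor
  (log-weight spread grows with $n$ times the parameter move), so each
  anchor step is limited to ±0.5 on the log covariance parameters and the
  estimator walks in re-anchored steps.
* **ESS floor.** A maximiser supported by a handful of dominating draws
  is Monte Carlo noise; steps whose weight effective sample size falls
  below 5% of the draws are backtracked towards the anchor. Without this
  the variance parameters drift systematically downhill along spurious
  "gains".
* **Convergence on identifiable quantities.** When $\phi$ is smaller than
  the closest inter-cluster distance — exactly the published regime,
  0.091 km against multi-km cluster spacing — the split of latent
  variance between $\sigma^2$ and $\tau^2$ (and $\phi$ itself) is
  likelihood-flat; only $\beta$ and $\sigma^2 + \tau^2$ are identified.
  Convergence is therefore declared on those quantities (or when an
  anchor's Monte Carlo likelihood gain falls below `gain_tol` with
  healthy weights), with the full parameter trace kept in the
  diagnostics; exhausting `max_anchors` warns rather than errors.

Optimisation is on $(\beta, \log\sigma^2, \log\phi, \log(\tau^2/\sigma^2))$:
an outer simplex search over range and noise ratio profiles an inner
quasi-Newton step over $(\beta, \log\sigma^2)$ with analytic gradients.
Standard errors: the $\beta$ block is the analytic Hessian of the Monte
Carlo objective with covariance parameters held at their estimates (the
usual near-orthogonality approximation); covariance-parameter standard
errors are reported on the log scale from a small numeric Hessian — the
published covariance "Std. Error" column exceeds its estimates, which is
consistent with a transformed scale, and the natural scale would be
meaningless for these right-skewed samplers anyway. Two performance
details are worth recording: correlations below $10^{-20}$ and importance
weights below $10^{-17}$ are flushed to exact zero, because subnormal
doubles make BLAS kernels an order of magnitude slower and produced
erratic sixty-second fits before the flush.

## 5. Prediction and exceedance maps

Prediction is plug-in: covariance parameters fixed at their estimates.
For each retained draw of $T$ at the data locations, $S$ at the grid is
drawn from the exact conditional Gaussian
$S(g) \mid T \sim N(c^\top \Sigma_T^{-1} T,\; \sigma^2 R_{gg} - c^\top \Sigma_T^{-1} c)$
with $c = \sigma^2 R_{gd}$ and $\Sigma_T = \sigma^2 R_{dd} + \tau^2 I$.
The mapped target is the spatially structured incidence
$\exp(d^\top\beta + S)$; the nugget is *excluded* from the predictive
target (it represents cluster-level noise, and the published probability
maps are smooth), with a documented switch (`include_nugget`) to add it
back. The point-estimate surface is the conditional *mean of the
exponential* (not the exponential of the mean) — unbiased for incidence
under the lognormal conditional; the source is silent on this choice.
Exceedance probabilities are the fraction of draws above the threshold;
maps classify locations hot (probability at least 0.7), cold (at most
0.3) or intermediate, boundaries inclusive. The published threshold sets
are 300/398/500 per 100 000 for bites around the national rate of 398,
and 100/151/250 for envenoming around 151.

## 6. The synthetic world

`make_domain()` builds a rectangular grid (default 240 x 400 km at 10 km
resolution, a Sri Lanka-sized island): elevation as a handful of seeded
Gaussian bumps scaled to [0, 2400] m (the country's relief ceiling);
log-normal population density declining with altitude; an agricultural
share anti-correlated with density and spread over roughly [0.01, 0.5] so
that the published 9% breakpoint is interior to the data; and three
contiguous climate bands. `sample_clusters()` partitions cells into
contiguous equal-cell strata (default 9, for the provinces), samples
clusters by simple random sampling without replacement (default 125 per
stratum, the published design), and draws sampled populations Poisson
around 148 persons — the published 165 665 people / 1118 clusters.
Outcome counts follow exactly the geostatistical model above with the
published parameter estimates as defaults
($\beta$ as printed; $\sigma^2 = 0.189$, $\phi = 0.091$ km,
$\tau^2 = 0.304$ for bites). Envenomings are binomial thinnings of bites
with probability $\min(1, \exp(\eta_{env} - \eta_{bite}))$ — this
preserves the envenoming marginal model wherever its rate is below the
bite rate and guarantees `y_envenoming <= y_bites`; the cap distorts the
envenoming margin in the few strata where the published envenoming rate
exceeds the bite rate.

What a green test does **not** establish: the generator's covariate
surfaces are declared stand-ins, not draws from Sri Lanka's covariate
joint distribution; there is no non-response, no household structure, no
NDVI/land-cover covariate, and cluster selection is equal-probability
within stratum rather than probability-proportional-to-size across
districts. Tests against this world validate the estimators' statistical
contracts, not the published point estimates, which are not reproducible
without the original microdata.

A consequence worth stating plainly, because the test suite reports it:
at the published parameter scale (mean cluster counts well below one) a
400-cluster survey only weakly identifies the total latent variance
$\sigma^2 + \tau^2$. An independent exact-likelihood oracle —
Gauss-Hermite marginal maximum likelihood, valid because $\phi = 0.091$
km makes the latent field effectively iid at multi-km cluster spacing —
shows median relative errors of roughly 40-50% across replicates on the
same simulated data sets. The MCML implementation tracks that oracle
closely (it is not an implementation artefact), so the parameter-recovery
acceptance criterion demanding a 30% median error is information-limited
in this stated world and is expected to stay red; the regression
coefficients are recovered comfortably within their standard errors.

## 7. Reproducibility

Every generator and sampler takes one integer seed; a master seed is
split deterministically per stage (domain, clusters, field, counts,
MCMC), so stages can be regenerated independently and a pipeline rerun
with the same seed writes byte-identical numeric artifacts. The pipeline
driver records seeds, package version, a config fingerprint and per-stage
wall time in `manifest.json`, and every file it writes is re-readable by
the package's own readers.
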