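---
title: "Community occupancy models with spatial replicates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community occupancy models with spatial replicates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commocc)
```

## The problem

Classical breeding-bird censuses record which species were detected along
1-km walking transects. A single visit cannot distinguish a species that
is absent from one that is present but missed, so naive occupancy maps
confound distribution with detectability. Repeat visits are the usual
remedy, but many historical surveys have none. `commocc` implements the
alternative of *spatial replication*: transects are grouped into grid
cells of 60 or 90 arc-seconds of longitude/latitude ("sites"), and the
1–7 transects falling inside a cell are treated as replicate surveys of
that cell. Under the closure assumption — the species' presence state is
constant across a cell during the survey period — replicates separate the
probability of occupancy from the probability of detection.

## The model

For site $i$ and species $k$, let $z_{i,k} \in \{0,1\}$ be the latent
presence state and $Y_{i,k}$ the number of the site's $J_i$ transects on
which the species was detected (the `Ysum` matrix). The hierarchical
model is

$$z_{i,k} \sim \mathrm{Bern}(\psi_{i,k}), \qquad
  Y_{i,k} \mid z_{i,k} \sim \mathrm{Bin}(J_i,\; p_k \, z_{i,k}),$$

$$\mathrm{logit}\,\psi_{i,k} = \delta_{0k} + \delta_{1k}\,\mathrm{FOREST}_i
  + \delta_{2k}\,\mathrm{FOREST}_i^2 + \delta_{3k}\,\mathrm{TEMP}_i
  + \delta_{4k}\,\mathrm{TEMP}_i^2 + \delta_{5k}\,\mathrm{PREC}_i,$$

with covariates standardized over sites. Detection is constant across
sites and replicates within a species. Because most species are sparse,
all species-level parameters are Normal random effects governed by
community hyperparameters:
$\delta_{mk} \sim N(\mu_{\delta_m}, \sigma_{\delta_m}^2)$ and
$\mathrm{logit}(p_k) \sim N(\mu_{lp}, \sigma_{lp}^2)$.

Two readings of the occupancy equation are possible because the logit of
$\psi$ is sometimes written with a site-by-species noise term. We treat
the linear predictor as deterministic given the species coefficients —
the per-cell variance of a single Bernoulli observation is not estimable
— and provide an optional logit-normal overdispersion term with a single
sd $\sigma_{lpsi}$ (`run_config(overdispersion = TRUE)`, default off) for
the literal reading. Similarly, a per-species detection variance is not
identifiable when each species has a single $p_k$; one community-level
pair $(\mu_{lp}, \sigma_{lp})$ is used.

"Uninformative" priors are made concrete as $N(0, 2.25^2)$ on every
hypermean (close to uniform on the probability scale after the inverse
logit) and $\mathrm{Unif}(0, 5)$ on every hyper-sd; both are settings of
`prior_config()`.

## Spatial aggregation

Grid cells are half-open squares `[edge, edge + cell)` whose edges sit at
integer multiples of the cell size from 0° — the origin is not part of
the survey design, so a fixed, reproducible convention is used and a
sensitivity check simply re-runs with a shifted origin. A transect is a
point (its mean position); it is never split across cells. Only cells
containing at least one transect become sites.

Site-level covariates are the mean of the raster cells whose centers fall
inside the site cell (`method = "mean"`), with center-point sampling
available as an alternative; the choice matters little at 2–3 raster
cells per site cell. Covariates are z-scored with the sample sd
(divisor $n-1$), and the quadratic columns are the element-wise squares
of the standardized linear columns — the convention of the community
occupancy literature, which keeps the intercept interpretable as the
"average site". The standardization constants are stored for prediction.

## The sampler

The model is fitted by a native Markov chain Monte Carlo sampler rather
than an external BUGS/JAGS engine:

* **Latent states.** Each $z_{i,k}$ has an exact Bernoulli full
  conditional: 1 when $Y_{i,k} > 0$, else
  $\psi(1-p)^J / (\psi(1-p)^J + 1 - \psi)$ — a Gibbs draw.
* **Species blocks.** Each species' $(\delta_{0..5,k})$ vector and its
  $\mathrm{logit}(p_k)$ move by random-walk Metropolis against the
  conditional posterior given $z$ (Bernoulli for presence, Binomial over
  occupied sites for detection). Step sizes adapt by Robbins–Monro toward
  ~35% acceptance during burn-in only, so retained draws come from a
  fixed transition kernel.
* **Collapsed ridge move.** Occupancy and detection trade off along a
  well-known ridge ($\psi\uparrow, p\downarrow$ fits sparse data almost
  equally well), and conditional-only updates cross it slowly because the
  discrete $z$ field must drift with them. Each sweep therefore also
  proposes a joint $(\delta_k, \mathrm{logit}\,p_k)$ random walk accepted
  against the *marginal* likelihood
  $\prod_i [\psi_{ik} p_k^{y}(1-p_k)^{J-y} + (1-\psi_{ik})\,1\{y=0\}]$,
  with $z$ redrawn from its full conditional immediately afterwards —
  a partially collapsed Gibbs composition that leaves the joint posterior
  invariant. In short-chain experiments this reduced hypermean
  $\widehat{R}$ from ≈1.3 to ≈1.02 at identical settings.
* **Hyperparameters.** Community means have conjugate Normal draws. The
  Uniform(0, u) prior on a sd implies a $v^{-1/2}$ density on the
  variance, so the variance update is inverse-gamma
  $((K-1)/2,\; SS/2)$ truncated to $v < u^2$, sampled by inverse CDF on
  the precision.

Chains start from dispersed positions centred on naive empirical rates
(observed cell occupancy and detection frequency, plus unit-scale
chain-specific noise), with hyperparameters drawn from wide
distributions; per-chain RNG streams derive deterministically from
`(seed, chain_id)`, so any run is bit-reproducible. Defaults mirror
standard practice for this model family: 3 chains, 15,000 iterations,
burn-in 5,000, thinning 2 — 5,000 retained draws per chain. Convergence
is assessed with the classic whole-chain Gelman–Rubin statistic
($\widehat{R} = \sqrt{((n-1)/n\,W + B/n)/W}$, flag at 1.1), with
split-chain $\widehat{R}$ available by argument.

The sampler stores per-site richness draws
$N_{site,i} = \sum_k z_{i,k}$ (rather than the full $z$ array) because
site richness is the derived quantity the analysis reports; the full
latent array would be ~50× larger with no additional use downstream.

## Derived quantities

* `species_estimates()` — posterior mean/sd of $p_k$ and of the
  across-site average occupancy $\bar\psi_k$.
* `site_richness()` — posterior mean/sd of $N_{site,i}$; every draw
  respects the lower bound given by the species actually observed at the
  site.
* `community_response_curve()` — the community-mean occupancy profile
  along one standardized covariate with the others at 0, summarized with
  a 95% credible band.
* `community_means()` — community occupancy and detectability under two
  labelled definitions: the inverse-logit of the hypermeans (a typical
  species at an average site) and the posterior mean of the averaged
  probabilities. They differ under species heterogeneity (Jensen's
  inequality); the averaged-probability definition is the default
  display, and the mean community size reported for a fit averages
  per-site posterior means.
* `compare_schemes()` — Pearson correlations across species of the
  posterior-mean $p$ and $\bar\psi$ between two grid resolutions of the
  same survey.

## The synthetic-study generator

`simulate_study()` produces a complete survey with known truth,
structured like a regional forest-bird census: 377 transects over a
~1.5° × 1.5° region, 73 species, covariate rasters at 30″. Its pieces:

* **Landscape.** Each covariate is a linear spatial gradient plus three
  random low-frequency cosine waves, linearly rescaled to realistic
  ranges (FOREST clipped to [0, 100]%, TEMP ≈ 10.9–18.3 °C, PREC ≈
  275–580 mm/yr). Zero noise amplitude gives an exactly planar field,
  which the aggregation tests exploit as an analytic oracle.
* **Transects.** Clustered-uniform placement (cluster centres + Normal
  scatter, with a 10% uniform background). The defaults — 80 centres,
  25″ scatter, 90% clustering — were chosen so the replicate histogram at
  60″ matches the shape of real transect surveys: ~240 occupied cells
  from 377 transects, about two-thirds singletons, maximum 5–7 per cell.
* **Community and detections.** Species coefficients are drawn from the
  hyperparameter distributions — exactly the fitted model run forward, a
  precondition for valid recovery tests. Latent presence is generated at
  the analysis cell size, so closure holds by construction (a finer
  generation scale to study closure violation would be a straightforward
  extension; it is off because the model assumes closure). Detections are
  per-transect Bernoulli draws given presence.
* **Default truth.** The hypermeans in `sim_default_hyper()` give strong
  negative climate effects, a weak negative forest effect, and were
  calibrated once by Monte Carlo over the generator's own site
  distribution so the realized community mean occupancy and detection
  probability are both ≈ 0.4 (`mu_delta0 = -0.24`, `mu_lp = -0.49`) —
  the magnitude regional forest-bird analyses report.

What passing tests on these data do *not* show: robustness to closure
violation at coarse cells, spatially autocorrelated residual occupancy
beyond the covariates, survey-level detection heterogeneity (observer,
date), or misaligned/projected rasters. Real-data conclusions inherit
those caveats.

## Numerical choices and edge cases

* Cell assignment snaps coordinates within 1e-9 cells of an edge onto
  the edge before flooring, so decimally-exact edge points land in the
  upper cell regardless of binary rounding.
* `plogis(±x)` log-forms and a guarded `log1p(exp(x))` keep all
  likelihood evaluations finite; detection probabilities are clamped to
  `[1e-15, 1 - 1e-15]` inside Metropolis ratios only.
* A zero-probability observation makes `total_loglik` return `-Inf` with
  a warning rather than an error.
* Zero-variance covariates, empty draw objects, partial posterior files,
  species-set mismatches between schemes, and sites without covariate
  coverage are hard errors; sites with missing covariates can instead be
  dropped with a warning (`na_action = "drop"`).
* Degenerate $\widehat{R}$ (zero within-chain variance) returns `NA`
  with a warning.

## Problem sizes used in the validation suite

Exact identities (aggregation totals, likelihood normalization, retention
arithmetic) run on enumerable inputs. Oracle comparisons use 2-site ×
2-species toys, where the latent field can be summed exhaustively and
1-D posteriors integrated on a fine grid, at 10⁵ retained draws.
Parameter recovery runs 20 replicate default-scale studies (≈240 sites,
75 species) with 3 × 3,000-iteration chains; the cross-scheme comparison
fits one study at 60″ and 90″ with 3 × 2,500-iteration chains. These
short-chain settings are the package's validation sizes; analyses of real
data should use the full defaults.

## Known limitations

* Detection is constant across replicates; survey-level covariates on
  $p$ are out of scope.
* No data augmentation for never-observed species: the community is the
  observed species list, and richness estimates are conditional on it.
* No abundance (N-mixture) variant, no dynamic
  colonization–extinction structure, no reprojection or vector GIS: the
  supported raster format is the headered ASCII grid, in geographic
  coordinates.
* The conditional species blocks mix slowly on very small communities
  (≈10 species); the collapsed move mitigates but does not remove this —
  for such data, run longer chains and check $\widehat{R}$.
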