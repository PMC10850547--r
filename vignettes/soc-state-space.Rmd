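---
title: "Multi-pool state-space modelling of soil organic carbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pool state-space modelling of soil organic carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socbayes)
```

## The problem

Long-term agricultural trials measure total soil organic carbon (TOC,
Mg C/ha) a handful of times over decades, yet carbon-accounting
decisions need trajectories, trends and honest uncertainty. `socbayes`
embeds compartmental carbon-turnover models in a Bayesian hierarchical
state-space framework

$$p(Y, X, \theta) = p(Y \mid X, \theta)\, p(X \mid \theta)\, p(\theta),$$

where the latent process $X$ is the vector of annual pool masses, $Y$
the sparse noisy TOC measurements, and $\theta$ the decay rates,
transfer fractions, inert mass and noise scales. Everything the package
reports comes from the posterior $p(X, \theta \mid Y)$.

## Pool models

Four nested topologies are provided (`build_pool_structure()`):

* **one** — all SOC in one homogeneous decaying pool;
* **two** — adds an inert organic matter (IOM) pool that undergoes no
  biological transformation and stays constant at a mass that is itself
  estimated;
* **three** — splits the decomposable carbon into a main pool (C) and a
  microbial biomass pool (BIO); decayed C is partly assimilated by BIO,
  decayed BIO is re-assimilated, returned to C or respired;
* **five** — the full RothC-style partition DPM/RPM/BIO/HUM/IOM, with
  plant inputs split between DPM and RPM and decayed matter routed to
  BIO and HUM.

The process model is discretised to an **annual** step (trials are
annual; finer steps would add parameters without data to inform them).
A decaying pool retains the survival fraction $e^{-K}$ of its mass each
year; the decayed share $1 - e^{-K}$ is divided among destination pools
by transfer fractions, the remainder leaving as CO2. This is exact for
independent first-order decay and keeps the system linear, which the
inference machinery depends on; simultaneous within-year multi-pool
exchange is neglected (first-order operator splitting). Mass balance
holds identically: every simulated step satisfies
$\mathrm{TOC}(t) + \mathrm{input}(t) - \mathrm{TOC}(t+1) =
\mathrm{CO2}(t)$.

Process and observation noise are **additive Gaussian**. This is a
deliberate choice: it makes the pool sub-model conditionally
linear-Gaussian so the Kalman filter can marginalise it exactly.
Negative-mass excursions can then occur in forward simulation; they are
clipped to zero and counted (`attr(x, "clipped")`), never silently, and
no clipping happens inside the filter. The per-pool process noise is
allocated in proportion to nominal pool shares and normalised so that
`process_sd` is the TOC-scale standard deviation; a shared per-pool
scale would let the noise alone push the small BIO pool past its cap.

Transfer defaults where no site-specific information exists are RothC
conventions: plant input split DPM:RPM $= 0.59{:}0.41$, and the decayed
non-CO2 share split BIO:HUM $= 0.46{:}0.54$. All are overridable.

## Plant input sub-model

The nonlinear part of the model is the annual plant dry matter $X_W$:
in a cropped year $X_W = c\,\mathrm{rain}\cdot e^{\varepsilon}$ with
$\varepsilon \sim N(0, \sigma_W^2)$, and $X_W = 0$ in fallow or cleared
years; the carbon input is
$\mathrm{carbon\ content} \times \mathrm{residue\ fraction} \times X_W$.
Rainfall-proportional yield with multiplicative log-normal noise is the
simplest positive-valued stochastic crop model consistent with annual
management records; treatment-specific residue fractions encode that
hay cutting removes more biomass than grain harvest (defaults: grain
0.6, hay 0.3, wheat-pasture 0.7, pasture 0.8, sorghum 0.6, fallow and
cleared 0). Dry matter is treated as i.i.d. across years given rainfall
— no carry-over soil-moisture dynamics. An additive-Gaussian noise mode
exists purely so that tests can compare the particle filters against an
exact Kalman oracle on a fully linear-Gaussian model.

## Inference

Conditional on a realised input path the pool model is linear-Gaussian,
so the marginal likelihood factorises into a nonlinear part (input
paths, handled by a bootstrap particle filter) and a linear part
(pools, marginalised exactly by the Kalman filter). This
**Rao-Blackwellised particle filter** (`rbpf()`) has an important
computational property: the Kalman covariance recursion does not depend
on the inputs, so it is shared across particles and only the
per-particle means are propagated — the filter is a handful of small
matrix products per year regardless of particle count. Resampling is
stratified and is triggered at weight-update (observation) steps; at
equal weights stratified resampling is provably the identity
permutation, so skipping it between observations changes nothing.

Parameters are sampled by **correlated pseudo-marginal
Metropolis-Hastings** (`cpm_mcmc()`): the likelihood in the acceptance
ratio is the filter's unbiased estimate, and the auxiliary standard
normals behind consecutive estimates are correlated,
$u' = \rho u + \sqrt{1 - \rho^2}\,\epsilon$, which keeps the estimator
noise from stalling the chain at small particle counts. The default
$\rho = 0.99$ follows common correlated pseudo-marginal practice;
$\rho = 0$ recovers the standard pseudo-marginal sampler. Proposals are
independent Gaussian random walks on a prior-driven unconstrained scale
(log for positive parameters, logit for fractions, identity for
normally distributed ones) with the transform Jacobian included; the
default scale 0.25 gives roughly 20-40% acceptance on the bundled
synthetic worlds. Fields of one site share $\theta$ with independent
latent trajectories, so the joint likelihood is the product over
fields.

The microbial pool is biologically constrained to a small share of
TOC: trajectories with BIO exceeding **5% of TOC** in any year are
rejected. The boundary is inclusive (exactly 5% passes). The check is
applied inside the accept step — a Metropolis-accepted proposal has one
state trajectory drawn (particle input path plus backward Gaussian
pool draw) and is rejected if that trajectory breaches the cap. The
trajectory drawn at acceptance time is stored with each retained draw
(and therefore repeats while the chain is sticky);
`sample_posterior_states()` re-draws fresh trajectories per retained
draw, with bounded rejection under the cap. The acceptance-time
rejection makes the effective target the constrained model; we do not
correct for the (small) probability that the current point would also
fail its own redraw — the cap acts as a trajectory-level veto inside
the accept step rather than as a formally augmented target.

The initial state is given a Gaussian prior anchored at the first
observation: the decomposable mass is the first TOC value minus the
constant mass, allocated over decaying pools by fixed nominal shares
(one/two-pool: all C; three-pool: C 0.97, BIO 0.03; five-pool: DPM
0.01, RPM 0.12, BIO 0.03, HUM 0.84), with standard deviation
`x0_cv * mean + x0_sd_floor * share` (defaults 0.2 and 0.5 Mg C/ha).
All of this is overridable through the filter `control` list,
including an absolute `x0_mean`.

Priors (`prior()`, `prior_set()`, `default_priors()`) support
log-normal, normal, uniform and beta families with an informativeness
label. The package defaults are declared choices, not values from any
particular study: log-normal decay-rate priors centred on the
literature rates (C 0.1, DPM 10, RPM 0.3, BIO 0.66, HUM 0.02 per
year, sdlog 0.5), IOM mass log-normal around 4 Mg C/ha, log-normal
noise-scale priors.

## Model selection

Models are compared by leave-future-out cross-validation of the
expected log pointwise predictive density,

$$\mathrm{ELPD} = \sum_{t=L}^{T-1} \log p(Y_{t+1} \mid Y_{1:t}),
\qquad
p(Y_{t+1} \mid Y_{1:t}) \approx \frac{1}{S} \sum_{s=1}^S
p(Y_{t+1} \mid Y_{1:t}, \theta^s),$$

with $\theta^s$ drawn by refitting the sampler to $Y_{1:t}$ and each
conditional density estimated by a filter run extended one observation
event ahead. Folds are indexed by observation *events* — a calendar
year in which any field was measured — and fields measured in the same
year form one joint fold; multi-year gaps are predicted straight
through with no intermediate conditioning. $L$ is the minimum number of
events required before predicting; at desk scale the synthetic sites
have 3-6 events, so the pipeline defaults to `L = max(2, events - 3)`
while full-scale analyses would use larger values. `rank_models()`
orders candidates by ELPD and flags differences within twice the
combined Monte-Carlo standard error as indistinguishable. ELPD is used
rather than RMSE because it scores the whole predictive distribution,
which is the quantity of interest when the output feeds risk-aware
carbon accounting; an RMSE column can be derived from the fold table if
wanted.

The retained-draw arithmetic follows the reference configuration: 4
chains of 200,000 iterations, 80,000 burn-in, thinning every 30th draw
— 4,000 retained draws per chain. $S$ is taken per chain, with all
chains pooled for the predictive average. Fold refits in examples and
tests use the scaled-down geometry (2,000 iterations, 500 burn-in,
thin 5) for speed.

## Posterior summaries

`soc_change()` reports the change functional
$g = \mathrm{TOC}(t) - \mathrm{TOC}(1)$ over posterior trajectory
draws — its mean (negative values are expected carbon loss since the
first trial year), its $n{-}1$ sample variance, and empirical 2.5/97.5
percentiles. `credible_band()` gives per-year percentile bands
(defaults 2.5, 25, 50, 75, 97.5), computed per field.
`gelman_rubin()` implements the classic (non-split) potential scale
reduction factor, with the conventional $\hat R < 1.2$ convergence
flag; a split-chain variant is available via `split = TRUE` for
trend-sensitive checks. Sample variances use $n-1$ denominators
throughout.

## Synthetic worlds

`make_site()` generates complete sites — shared Gamma rainfall,
per-field dry matter, noisy latent pool trajectories, sparse TOC
observations — with the truths returned for recovery testing.
`tarlee_template()` encodes a 1979-1997 Mediterranean-climate cereal
trial: three fields (continuous wheat; wheat-fallow; wheat-pasture, hay
cuts 1988-89, closing fallow), observations in 1979, 1985 and 1996,
355 mm mean growing-season rain. `brigalow_template()` encodes a
semi-arid subtropical site cleared in 1982 and cropped for 18 years
(fallow 1983/1993, sorghum 1984/1995/1997/1999, wheat otherwise); its
observation years are synthetic stand-ins since the source records do
not enumerate them, and its 500 mm growing-season mean is likewise a
declared stand-in. Field depth structure is collapsed to a single
0-30 cm Mg C/ha stock, the quantity the models operate on. Default
magnitudes (initial TOC 45 Mg C/ha, IOM around 10% of it) keep the
microbial cap and recovery tests non-degenerate.

What a green synthetic test does **not** establish: the generator
shares the model family with the fitted models, so it validates the
machinery (filters, sampler, cross-validation), not the biogeochemical
adequacy of any topology for real soils; real data bring rate
modifiers (temperature, moisture, clay), sampling-depth artefacts and
treatment effects the input model does not emulate.

## Numerical choices

* Degenerate observation variances are treated as exact constraints
  (log-likelihood contribution 0 on match, $-\infty$ otherwise, with a
  $10^{-6}$ match tolerance).
* Backward sampling uses Cholesky factorisations; on failure
  (rank-deficient covariances, e.g. zero process noise) it falls back
  to a symmetric pseudo-inverse/eigenvalue path in which degenerate
  directions collapse to the smoother mean.
* Covariances are symmetrised after every update; positive
  semi-definiteness of user-supplied covariances is checked on entry
  (eigenvalue tolerance `1e-8` relative).
* Proposals outside the admissible region (route fractions of a source
  summing past 1, negative masses under a normal prior) are rejected
  before any filtering.
* All randomness flows through R's RNG from user seeds; chain $c$ uses
  `seed + (c-1) * 100003`, and identical seeds reproduce runs
  bit-for-bit.

## Known limitations

* No rate modifiers: decay rates are constant across years, so
  climate-driven decomposition variability is absorbed by process
  noise.
* The microbial cap is enforced by rejection, not by a dynamic
  microbial growth model; heavy truncation would distort the BIO
  posterior if the data pushed against the cap persistently.
* Full-scale chain geometry (4 × 200,000 iterations per fold) is
  computationally serious; everything in the examples and tests uses
  declared scaled-down geometries.
* LFO-CV refits the sampler per fold; for long series an importance
  -sampling approximation would be preferable, and is out of scope
  here.

## A short end-to-end run

```{r example, eval = FALSE}
syn <- make_site(tarlee_template(n_fields = 1, seed = 1,
                                 obs_years = c(1979, 1983, 1987, 1991,
                                               1994, 1997)))
st <- build_pool_structure("three")
priors <- default_priors(st, include = c("decay", "iom"))
cfg <- soc_mcmc_config(iterations = 6000, burn_in = 2000, thin = 5,
                       n_chains = 2, n_particles = 32, seed = 1)
trace <- cpm_mcmc(st, syn$sites[[1]], priors, cfg)
gelman_rubin(trace)
soc_change(toc_draws(trace, 1))
```
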