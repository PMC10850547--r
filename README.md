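# socbayes

Bayesian multi-pool state-space modelling of soil organic carbon (SOC)
for sparse agricultural time series.

Long-term field trials typically measure total SOC a handful of times
over two decades. `socbayes` is for modellers and carbon-accounting
analysts who need, from such data, a posterior over the whole carbon
trajectory — how much carbon a field gained or lost, with honest
uncertainty — and a principled way to decide how much model complexity
those few observations can support.

## What it implements

Four compartmental carbon models (one-pool; two-pool with an inert IOM
pool; three-pool adding a microbial biomass pool BIO capped at 5% of
TOC; a RothC-like five-pool DPM/RPM/BIO/HUM/IOM), embedded in the
Bayesian hierarchical state-space factorisation

    p(Y, X, θ) = p(Y | X, θ) p(X | θ) p(θ)

with annual first-order decay (survival fraction e^-K, decayed mass
routed by transfer fractions, remainder emitted as CO2), a stochastic
rainfall-driven plant-input sub-model, and sparse TOC observations
Y = TOC + noise.

Inference is correlated pseudo-marginal Metropolis–Hastings whose
likelihood estimates come from a Rao-Blackwellised particle filter:
bootstrap particles carry plant-input paths, and conditional on each
path the linear pool sub-model is marginalised exactly by a Kalman
filter. Model comparison is leave-future-out cross-validation of the
expected log predictive density

    ELPD = Σ_{t=L}^{T-1} log p(Y_{t+1} | Y_{1:t}),

and summaries cover SOC-change functionals g = TOC(t) − TOC(1),
percentile bands, and Gelman–Rubin R̂ (< 1.2 convergence flag). A
synthetic-site generator with Mediterranean ("tarlee") and semi-arid
subtropical ("brigalow") templates makes every stage runnable without
field data.

## Worked example

```r
library(socbayes)

syn <- make_site(tarlee_template(n_fields = 1, seed = 1,
                                 obs_years = c(1979, 1983, 1987, 1991,
                                               1994, 1997)))
st     <- build_pool_structure("three")
priors <- default_priors(st, include = c("decay", "iom"))
cfg    <- soc_mcmc_config(iterations = 6000, burn_in = 2000, thin = 5,
                          n_chains = 2, n_particles = 32, seed = 1)
trace  <- cpm_mcmc(st, syn$sites[[1]], priors, cfg)
trace
#> CPM trace: three-pool model, 2 chain(s) x 800 retained draws
#>   parameters: K_C, K_BIO, iom_mass
#>   acceptance: 29.0%, 29.3%
gelman_rubin(trace)
#>   parameter     rhat converged
#> 1       K_C 1.001529      TRUE
#> 2     K_BIO 1.011240      TRUE
#> 3  iom_mass 0.999378      TRUE
tail(soc_change(toc_draws(trace, 1)), 1)
#>    year mean_change var_change      p2.5     p97.5
#> 19 1997   -22.39916   3.475198 -26.09502 -18.82987
```

Reading the output: the chains agree (all R̂ < 1.2 — no evidence of
non-convergence), and this synthetic wheat field is estimated to have
lost about 22.4 Mg C/ha between 1979 and 1997 (negative change =
carbon loss), with a 95% credible interval of −26.1 to −18.8.
Candidate topologies
are compared with `lfo_cv()` on each and `rank_models()` on the
results; larger ELPD wins, and differences within twice the combined
Monte-Carlo error are flagged as indistinguishable.

A thin command-line front end over the same functions lives at
`inst/cli/socbayes` (subcommands `simulate`, `fit`, `select`,
`diagnose`; plain CSV/JSON in and out, with a replayable manifest).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end workflow from scratch at a
scaled-down size: it simulates a synthetic Tarlee-style site, fits the
three-pool model by correlated pseudo-marginal MCMC, reports
convergence diagnostics and the posterior SOC change, runs the
leave-future-out comparison of the three-pool against the one-pool
model, and writes its JSON output to `--out`.
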