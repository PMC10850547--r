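# Shared synthetic worlds and toy models used across test files.

# Conjugate normal-mean toy realised inside the SOC machinery:
# two-pool model with the C pool pinned at zero (x0_mean = 0, no
# process noise, all-fallow schedule) so y_t ~ N(iom_mass, sigma^2)
# exactly and the posterior under a normal prior is available in
# closed form.
conjugate_world <- function(n_obs = 5, sigma = 2, mu0 = 40, tau0 = 5,
                            mu_true = 42, seed = 99) {
  set.seed(seed)
  yrs <- 2001:(2000 + 2 * n_obs)
  oy <- yrs[seq(1, by = 2, length.out = n_obs)]
  y <- rnorm(n_obs, mu_true, sigma)
  st <- build_pool_structure("two")
  pars <- default_parameters(st, process_sd = 0, obs_sd = sigma,
                             iom_mass = mu0)
  site <- soc_site(1, yrs, rep("fallow", length(yrs)),
                   rep(300, length(yrs)),
                   data.frame(year = oy, toc = y))
  list(structure = st, params = pars, site = site, y = y, obs_years = oy,
       sigma = sigma, mu0 = mu0, tau0 = tau0,
       control = list(x0_mean = 0, x0_cv = 0, x0_sd_floor = 0),
       priors = prior_set(iom_mass = prior("normal", mean = mu0,
                                           sd = tau0)))
}

# closed-form conjugate posterior (mean, var) after observing yy
conjugate_posterior <- function(yy, sigma, mu0, tau0) {
  tn2 <- 1 / (1 / tau0^2 + length(yy) / sigma^2)
  c(mean = tn2 * (mu0 / tau0^2 + sum(yy) / sigma^2), var = tn2)
}

# three-pool synthetic world for parameter recovery: one field, 20
# years of continuous wheat, 6 TOC observations, truths at the package
# default prior medians
recovery_world <- function(seed) {
  st <- build_pool_structure("three")
  truth <- default_parameters(st)  # K_C 0.1, K_BIO 0.66, iom 4
  cfg <- site_config(n_fields = 1, years = 1978:1997,
                     treatments = "wheat_grain",
                     obs_years = c(1978, 1982, 1986, 1990, 1993, 1997),
                     model_id = "three", params = truth, x0_toc = 45,
                     seed = seed)
  syn <- make_site(cfg)
  list(structure = st, truth = truth, site = syn$sites[[1]], syn = syn,
       priors = prior_set(
         K_C = prior("lognormal", meanlog = log(0.1), sdlog = 0.5),
         K_BIO = prior("lognormal", meanlog = log(0.66), sdlog = 0.5),
         iom_mass = prior("lognormal", meanlog = log(4), sdlog = 0.5)))
}

# two-pool world with a strong inert floor (IOM ~ 44% of initial TOC)
# for model-selection recovery against the one-pool model
strong_iom_world <- function(seed) {
  st <- build_pool_structure("two")
  truth <- default_parameters(st, decay_rates = c(C = 0.15),
                              iom_mass = 20, process_sd = 0.5, obs_sd = 1)
  cfg <- site_config(n_fields = 1, years = 1982:1999,
                     treatments = "cleared",
                     obs_years = c(1982, 1985, 1988, 1991, 1994, 1997),
                     model_id = "two", params = truth, x0_toc = 45,
                     seed = seed)
  list(structure = st, truth = truth, syn = make_site(cfg))
}

# scalar AR(1)-plus-noise toy as a generic bootstrap_pf model; obs at
# every year
bpf_toy_model <- function(a = 0.8, q_sd = 1, r_sd = 1, m0 = 0, p0_sd = 1,
                          y) {
  T_len <- length(y)
  list(T_len = T_len,
       init = function(z0) matrix(m0 + p0_sd * z0[, 1], nrow = 1),
       trans = function(X, t, Z) a * X + q_sd * t(Z),
       obs_loglik = function(X, t) dnorm(y[t], drop(X), r_sd, log = TRUE),
       d_innov = 1L, d_init = 1L,
       kf_args = list(A = matrix(a), b = 0, Q = matrix(q_sd^2), H = 1,
                      R = r_sd^2, m0 = m0, P0 = matrix(p0_sd^2),
                      inputs = rep(0, T_len - 1L), y = y,
                      obs_at = seq_len(T_len)))
}

# small MCMC configuration for fast tests
tiny_mcmc <- function(...) {
  do.call(soc_mcmc_config,
          modifyList(list(iterations = 600, burn_in = 200, thin = 4,
                          n_chains = 1, n_particles = 8, rho = 0.99,
                          seed = 1), list(...)))
}
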