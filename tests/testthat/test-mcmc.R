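test_that("microbial cap check handles boundary and missing-pool cases", {
  tr <- data.frame(year = 1:3, BIO = c(1, 1, 1), toc = c(30, 30, 30))
  expect_true(check_bio_constraint(tr))
  tr$BIO[2] <- 0.06 * 30            # 6% in one year
  expect_false(check_bio_constraint(tr))
  tr$BIO <- 0                       # empty pool
  expect_true(check_bio_constraint(tr))
  tr$BIO <- 0.05 * tr$toc           # exactly 5%: boundary inclusive
  expect_true(check_bio_constraint(tr))
  no_bio <- data.frame(year = 1:2, C = c(5, 5), toc = c(5, 5))
  expect_warning(ok <- check_bio_constraint(no_bio), "no BIO pool")
  expect_true(ok)
})

test_that("configuration validation and the retained-draw formula hold", {
  expect_error(soc_mcmc_config(iterations = 100, burn_in = 100), "burn_in")
  expect_error(soc_mcmc_config(thin = 0), "thin")
  expect_error(soc_mcmc_config(rho = 1), "rho")
  # full-scale geometry: (200000 - 80000) / 30 = 4000 retained per chain
  cfg <- soc_mcmc_config()
  expect_equal((cfg$iterations - cfg$burn_in) %/% cfg$thin, 4000)
  expect_equal(cfg$n_chains, 4)
  # same arithmetic exercised end-to-end at a tiny scale
  w <- conjugate_world()
  cfg <- tiny_mcmc(iterations = 200, burn_in = 80, thin = 30,
                   n_particles = 1)
  trace <- cpm_mcmc(w$structure, w$site, w$priors, cfg,
                    base_params = w$params, control = w$control,
                    proposal_scales = c(iom_mass = 2))
  expect_equal(nrow(trace$chains[[1]]$draws), 4)
  expect_length(trace$chains[[1]]$trajectories, 4)
})

test_that("chain posterior matches the conjugate closed form", {
  w <- conjugate_world()
  post <- conjugate_posterior(w$y, w$sigma, w$mu0, w$tau0)
  cfg <- soc_mcmc_config(iterations = 6000, burn_in = 1000, thin = 2,
                         n_chains = 1, n_particles = 1, rho = 0.99,
                         seed = 7, store_states = FALSE)
  trace <- cpm_mcmc(w$structure, w$site, w$priors, cfg,
                    base_params = w$params, control = w$control,
                    proposal_scales = c(iom_mass = 2))
  draws <- retained_draws(trace)[, "iom_mass"]
  # conservative effective-sample-size allowance for the random walk
  tol_mean <- 5 * sqrt(post["var"] / (length(draws) / 20))
  expect_lt(abs(mean(draws) - post["mean"]), tol_mean)
  expect_lt(abs(var(draws) - post["var"]) / post["var"], 0.3)
})

test_that("identical seeds reproduce chains bit-for-bit, for any rho", {
  w <- conjugate_world()
  for (rho in c(0, 0.99)) {
    cfg <- tiny_mcmc(n_particles = 1, rho = rho, seed = 11)
    t1 <- cpm_mcmc(w$structure, w$site, w$priors, cfg,
                   base_params = w$params, control = w$control)
    t2 <- cpm_mcmc(w$structure, w$site, w$priors, cfg,
                   base_params = w$params, control = w$control)
    expect_identical(t1$chains[[1]]$draws, t2$chains[[1]]$draws)
    expect_identical(t1$chains[[1]]$loglik, t2$chains[[1]]$loglik)
  }
})

test_that("stored three-pool trajectories always satisfy the microbial cap", {
  w <- recovery_world(5)
  cfg <- tiny_mcmc(iterations = 800, burn_in = 200, thin = 3,
                   n_particles = 16, seed = 2)
  trace <- cpm_mcmc(w$structure, w$site, w$priors, cfg)
  for (trajs in trace$chains[[1]]$trajectories) {
    tr <- trajs[[1]]
    expect_true(all(tr$BIO <= 0.05 * tr$toc))
  }
  tm <- toc_draws(trace, 1)
  expect_equal(dim(tm), c(200, 20))
})

test_that("posterior state draws collapse to the deterministic path without noise", {
  st <- build_pool_structure("three")
  pars <- default_parameters(st, process_sd = 0, obs_sd = 0)
  ip0 <- input_params(input_sd_log = 0)
  x0 <- c(C = 38, BIO = 1.2, IOM = 4)
  yrs <- 1990:1999
  rain <- rep(350, 10)
  xw <- simulate_dry_matter(rain, rep("wheat_grain", 10), ip0)
  inputs <- carbon_input(xw, rep("wheat_grain", 10), ip0)
  det <- simulate_process(st, pars, inputs[-10], x0)
  oy <- c(1990, 1995, 1999)
  site <- soc_site(1, yrs, rep("wheat_grain", 10), rain,
                   data.frame(year = oy, toc = det$toc[match(oy, yrs)]))
  fake <- structure(list(
    chains = list(list(draws = matrix(0.1, 3, 1,
                                      dimnames = list(NULL, "K_C")))),
    param_names = "K_C",
    config = tiny_mcmc(n_particles = 1), model_id = "three"),
    class = "soc_trace")
  ctrl <- list(x0_mean = unname(x0[c("C", "BIO")]), x0_cv = 0,
               x0_sd_floor = 0)
  ssd <- sample_posterior_states(fake, st, site, base_params = pars,
                                 base_iparams = ip0, n_particles = 1,
                                 seed = 3, control = ctrl)
  for (tr in ssd$fields[[1]])
    expect_equal(tr$toc, det$toc, tolerance = 1e-8)
})

test_that("posterior state draws match the closed-form smoother moments", {
  # one-pool, deterministic inputs: the state posterior is exactly the
  # linear-Gaussian smoother
  st <- build_pool_structure("one")
  pars <- default_parameters(st, decay_rates = c(C = 0.15),
                             process_sd = 0.8, obs_sd = 1.2)
  ip0 <- input_params(input_sd_log = 0)
  yrs <- 1990:1997
  rain <- rep(320, 8)
  sched <- rep("wheat_grain", 8)
  inputs <- carbon_input(simulate_dry_matter(rain, sched, ip0), sched, ip0)
  set.seed(12)
  y <- c(40, 36.5, 35.2)
  oy <- c(1990, 1994, 1997)
  site <- soc_site(1, yrs, sched, rain, data.frame(year = oy, toc = y))
  m0 <- 40; p0 <- 4
  ctrl <- list(x0_mean = m0, x0_cv = 0, x0_sd_floor = sqrt(p0))
  n_draws <- 400
  fake <- structure(list(
    chains = list(list(draws = matrix(0.15, n_draws, 1,
                                      dimnames = list(NULL, "K_C")))),
    param_names = "K_C",
    config = tiny_mcmc(n_particles = 1), model_id = "one"),
    class = "soc_trace")
  ssd <- sample_posterior_states(fake, st, site, base_params = pars,
                                 base_iparams = ip0, n_particles = 1,
                                 seed = 8, control = ctrl)
  draws <- t(vapply(ssd$fields[[1]], `[[`, numeric(8), "C"))
  sm <- rts_smoother_1d(a = exp(-0.15), b = 1, q = 0.8^2, r = 1.2^2,
                        m0 = m0, p0 = p0, inputs = inputs[-8], y = y,
                        obs_at = match(oy, yrs))
  for (t in 1:8) {
    se_m <- sqrt(sm$var[t] / n_draws)
    expect_lt(abs(mean(draws[, t]) - sm$mean[t]), 4 * se_m)
    expect_lt(abs(var(draws[, t]) - sm$var[t]),
              4 * sm$var[t] * sqrt(2 / (n_draws - 1)))
  }
})

test_that("prior evaluation covers the supported families", {
  ps <- prior_set(u = prior("uniform", min = 0, max = 1),
                  ln = prior("lognormal", meanlog = 0, sdlog = 1))
  expect_equal(log_prior(c(u = 0.5), prior_set(u = ps$u)), 0)
  expect_identical(log_prior(c(u = 1.5), prior_set(u = ps$u)), -Inf)
  expect_equal(log_prior(c(ln = 1), prior_set(ln = ps$ln)),
               -log(sqrt(2 * pi)), tolerance = 1e-10)
  expect_error(log_prior(c(zz = 1), ps), "no prior")
})
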