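test_that("minimal series yields exactly one fold", {
  w <- conjugate_world(n_obs = 3)
  cfg <- tiny_mcmc(n_particles = 1, store_states = FALSE)
  el <- lfo_cv(w$structure, w$site, w$priors, L = 2, config = cfg,
               base_params = w$params, control = w$control,
               proposal_scales = c(iom_mass = 2))
  expect_equal(nrow(el$folds), 1)
  expect_equal(el$folds$year, w$obs_years[3])
  expect_equal(el$elpd_total, el$folds$log_pred)
})

test_that("L out of range is rejected", {
  w <- conjugate_world(n_obs = 3)
  cfg <- tiny_mcmc(n_particles = 1)
  expect_error(lfo_cv(w$structure, w$site, w$priors, L = 3, config = cfg),
               "must be smaller")
  expect_error(lfo_cv(w$structure, w$site, w$priors, L = 5, config = cfg),
               "must be smaller")
})

test_that("ELPD matches the analytic conjugate fold densities", {
  w <- conjugate_world(n_obs = 5, seed = 99)
  # analytic: each fold's predictive is N(mu_t, tau_t^2 + sigma^2)
  an <- vapply(2:4, function(t) {
    p <- conjugate_posterior(w$y[1:t], w$sigma, w$mu0, w$tau0)
    dnorm(w$y[t + 1], p["mean"], sqrt(p["var"] + w$sigma^2), log = TRUE)
  }, numeric(1))
  cfg <- soc_mcmc_config(iterations = 3000, burn_in = 800, thin = 2,
                         n_chains = 1, n_particles = 1, rho = 0.99,
                         seed = 7, store_states = FALSE)
  el <- lfo_cv(w$structure, w$site, w$priors, L = 2, config = cfg,
               base_params = w$params, control = w$control,
               proposal_scales = c(iom_mass = 2), max_pred_draws = 400)
  expect_equal(el$folds$log_pred, an, tolerance = 0.05)
  expect_lt(abs(el$elpd_total - sum(an)), 0.1)
})

test_that("folds never see the future (sentinel perturbation)", {
  w <- conjugate_world(n_obs = 4, seed = 13)
  cfg <- tiny_mcmc(n_particles = 1, store_states = FALSE, seed = 21)
  el1 <- lfo_cv(w$structure, w$site, w$priors, L = 2, config = cfg,
                base_params = w$params, control = w$control,
                proposal_scales = c(iom_mass = 2))
  # perturb the last observation: fold predicting event 3 must not move
  site2 <- w$site
  site2$obs$toc[4] <- site2$obs$toc[4] + 25
  el2 <- lfo_cv(w$structure, site2, w$priors, L = 2, config = cfg,
                base_params = w$params, control = w$control,
                proposal_scales = c(iom_mass = 2))
  expect_identical(el1$folds$log_pred[1], el2$folds$log_pred[1])
  expect_false(el1$folds$log_pred[2] == el2$folds$log_pred[2])
})

test_that("predictive density requires posterior draws and reduces at S = 1", {
  w <- conjugate_world(n_obs = 4, seed = 17)
  cfg <- tiny_mcmc(n_particles = 1, store_states = FALSE)
  hist_site <- socbayes:::truncate_obs(w$site, w$obs_years[3])
  trace <- cpm_mcmc(w$structure, hist_site,
                    w$priors, cfg, base_params = w$params,
                    control = w$control, proposal_scales = c(iom_mass = 2))
  pd1 <- predictive_density(trace, w$structure, w$site,
                            history_upto = w$obs_years[3],
                            next_year = w$obs_years[4],
                            base_params = w$params, control = w$control,
                            seed = 5, max_draws = 1)
  expect_length(pd1$per_draw, 1)
  expect_equal(pd1$mean, pd1$per_draw[1])
  expect_true(is.na(pd1$se))   # single draw: no spread estimate
})

test_that("model ranking orders by ELPD and flags close calls", {
  mk <- function(id, lp, se) {
    structure(list(model_id = id, L = 2,
                   folds = data.frame(year = c(2005, 2007),
                                      log_pred = lp, se_log = se),
                   elpd_total = sum(lp), mc_se = sqrt(sum(se^2))),
              class = "elpd_result")
  }
  a <- mk("three", c(-17, -17.79), c(0.1, 0.1))   # total -34.79
  b <- mk("one", c(-26, -27.02), c(0.1, 0.1))     # total -53.02
  r <- rank_models(list(b, a))
  expect_equal(r$model_id, c("three", "one"))
  expect_equal(r$elpd, c(-34.79, -53.02))
  expect_false(r$indistinguishable_from_best[2])
  # close pair within 2 * combined MC error is flagged
  c2 <- mk("two", c(-17.05, -17.8), c(0.3, 0.3))  # total -34.85
  r2 <- rank_models(list(a, c2))
  expect_true(r2$indistinguishable_from_best[2])
  # singleton passes through
  r3 <- rank_models(list(a))
  expect_equal(nrow(r3), 1)
  # mismatched folds rejected
  d <- mk("five", c(-1, -2), c(0.1, 0.1))
  d$folds$year <- c(2001, 2003)
  expect_error(rank_models(list(a, d)), "different fold sets")
})
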