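test_that("stratified resampling is exact under equal weights", {
  expect_identical(stratified_resample(rep(1, 7), 0.42), 1:7)
  # and unbiased in general: resampled frequency tracks the weights
  set.seed(1)
  w <- c(0.5, 0.2, 0.2, 0.1)
  counts <- table(factor(unlist(lapply(runif(4000),
    function(u) stratified_resample(w, u))), levels = 1:4))
  expect_equal(as.numeric(counts) / sum(counts), w, tolerance = 0.02)
})

test_that("auxiliary blocks correlate as rho * old + sqrt(1-rho^2) * new", {
  set.seed(8)
  a <- aux_block(200, 50)
  b <- correlate_aux(a, 0.9)
  expect_identical(dim(a$z), dim(b$z))
  cc <- cor(as.vector(a$z), as.vector(b$z))
  expect_lt(abs(cc - 0.9), 0.02)
  expect_lt(abs(sd(as.vector(b$z)) - 1), 0.02)  # marginal stays N(0,1)
  z <- correlate_aux(a, 0)
  expect_lt(abs(cor(as.vector(a$z), as.vector(z$z))), 0.05)
})

test_that("bootstrap filter is exact for deterministic dynamics", {
  set.seed(3)
  y <- c(1.2, 0.7, 1.5, 0.9)
  # zero innovation and initial noise: all particles identical
  model <- bpf_toy_model(a = 0.8, q_sd = 0, r_sd = 1, m0 = 1, p0_sd = 0,
                         y = y)
  exact <- do.call(kalman_filter, model$kf_args)$loglik
  for (N in c(1, 7, 60)) {
    est <- bootstrap_pf(model, N, aux_block(N, model$T_len, 1, 1))$loglik
    expect_equal(est, exact, tolerance = 1e-12)
  }
})

test_that("one particle reduces to a single-path importance estimate", {
  set.seed(4)
  y <- rnorm(5)
  model <- bpf_toy_model(y = y)
  aux <- aux_block(1, model$T_len, 1, 1)
  est <- bootstrap_pf(model, 1, aux)$loglik
  # direct single-trajectory computation with the same aux draws
  x <- 0 + 1 * aux$z0[1, 1]
  ll <- dnorm(y[1], x, 1, log = TRUE)
  for (t in 2:5) {
    x <- 0.8 * x + aux$z[1, t - 1, 1]
    ll <- ll + dnorm(y[t], x, 1, log = TRUE)
  }
  expect_equal(est, ll, tolerance = 1e-12)
})

test_that("bootstrap filter likelihood estimator is unbiased", {
  set.seed(5)
  y <- rnorm(5, 0, 1.3)
  model <- bpf_toy_model(y = y)
  exact <- exp(do.call(kalman_filter, model$kf_args)$loglik)
  ests <- replicate(300,
    exp(bootstrap_pf(model, 100, aux_block(100, 5, 1, 1))$loglik))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - exact), 3 * se)
})

test_that("RBPF with deterministic inputs equals a single Kalman run", {
  w <- recovery_world(17)
  pars <- w$truth
  ip0 <- input_params(input_sd_log = 0)
  ref <- rbpf(w$structure, pars, ip0, w$site, 1)
  for (N in c(3, 25)) {
    est <- rbpf(w$structure, pars, ip0, w$site, N)
    expect_equal(est$loglik, ref$loglik, tolerance = 1e-12)
  }
  # identical aux => identical estimate under input noise
  ip <- input_params(input_sd_log = 0.3)
  set.seed(6)
  aux <- aux_block(20, length(w$site$years))
  e1 <- rbpf(w$structure, pars, ip, w$site, 20, aux = aux)$loglik
  e2 <- rbpf(w$structure, pars, ip, w$site, 20, aux = aux)$loglik
  expect_identical(e1, e2)
})

test_that("RBPF agrees with a joint bootstrap filter over inputs and pools", {
  # three-pool site; the joint filter propagates pool masses with both
  # input and process innovations, the RBPF marginalises the pools
  w <- recovery_world(23)
  st <- w$structure; pars <- w$truth
  ip <- input_params(input_sd_log = 0.3)
  s <- w$site
  T_all <- length(s$years)
  sys <- build_linear_system(st, pars)
  dec <- sys$decaying_idx
  A <- sys$A[dec, dec]; b <- sys$b[dec]
  qsd <- sqrt(diag(sys$Q)[dec])
  offset <- sum(sys$const_mass)
  ctrl <- socbayes:::filter_control(list())
  shares <- socbayes:::default_x0_shares(st)[st$decaying]
  m0 <- pmax(s$obs$toc[1] - offset, 0.5) * as.numeric(shares)
  p0_sd <- ctrl$x0_cv * m0 + ctrl$x0_sd_floor * as.numeric(sys$noise_weights)
  cf <- ip$carbon_content * unname(ip$residue_fraction[s$treatments])
  base <- ip$yield_coef * s$rain_mm
  crop <- s$treatments %in% c("wheat_grain", "wheat_hay", "wheat_pasture",
                              "pasture", "sorghum")
  obs_t <- match(s$obs$year, s$years)
  ymap <- setNames(s$obs$toc, obs_t)
  d <- length(dec)
  joint_model <- list(
    T_len = T_all,
    init = function(z0) m0 + p0_sd * t(z0),
    trans = function(X, t, Z) {
      u <- if (crop[t]) cf[t] * base[t] * exp(ip$input_sd_log * Z[, 1]) else 0
      A %*% X + outer(b, u * rep(1, ncol(X))[seq_len(ncol(X))]) +
        qsd * t(Z[, 1 + seq_len(d), drop = FALSE])
    },
    obs_loglik = function(X, t) {
      if (!t %in% obs_t) return(NULL)
      dnorm(ymap[[as.character(t)]], colSums(X) + offset, sqrt(sys$R),
            log = TRUE)
    })
  set.seed(9)
  N <- 80
  n_rep <- 120
  joint_ll <- replicate(n_rep,
    bootstrap_pf(joint_model, N, aux_block(N, T_all, 1 + d, d))$loglik)
  rb_ll <- replicate(n_rep,
    rbpf(st, pars, ip, s, N)$loglik)
  # both unbiased for the same likelihood: means agree within MC error
  se <- sqrt(var(exp(joint_ll)) / n_rep + var(exp(rb_ll)) / n_rep)
  expect_lt(abs(mean(exp(joint_ll)) - mean(exp(rb_ll))), 4 * se)
  # Rao-Blackwellisation reduces estimator variance
  expect_lt(var(rb_ll), var(joint_ll))
})

test_that("degenerate weights flag the estimate as impossible", {
  # bounded observation window that no particle can reach
  model <- list(T_len = 2,
                init = function(z0) matrix(0.1 * z0[, 1], nrow = 1),
                trans = function(X, t, Z) X + 0.1 * t(Z),
                obs_loglik = function(X, t)
                  dunif(100, drop(X) - 1, drop(X) + 1, log = TRUE))
  out <- bootstrap_pf(model, 20, aux_block(20, 2, 1, 1))
  expect_identical(out$loglik, -Inf)
  expect_true(out$degenerate)
})
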