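test_that("pool topologies match their definitions", {
  one <- build_pool_structure("one")
  expect_identical(one$pools, "C")
  expect_length(one$routes$C, 0)          # all decayed mass leaves as CO2

  two <- build_pool_structure("two")
  expect_identical(two$pools, c("C", "IOM"))
  expect_identical(two$constant, "IOM")
  expect_false("IOM" %in% names(two$routes))  # inert: no routes in or out

  three <- build_pool_structure("three")
  expect_setequal(three$pools, c("C", "BIO", "IOM"))
  # BIO decay splits between re-assimilation, the main pool and CO2
  expect_setequal(names(three$routes$BIO), c("BIO", "C"))

  five <- build_pool_structure("five")
  expect_identical(five$pools, c("DPM", "RPM", "BIO", "HUM", "IOM"))
  expect_setequal(names(five$input_split), c("DPM", "RPM"))
  expect_setequal(names(five$routes$DPM), c("BIO", "HUM"))
  expect_setequal(names(five$routes$RPM), c("BIO", "HUM"))

  expect_error(build_pool_structure("four"), "unknown model_id")
})

test_that("annual discretisation reproduces hand-computed decay", {
  st <- build_pool_structure("three")
  pp <- default_parameters(st, decay_rates = c(C = 0.1, BIO = 0.66),
                           transfer_fractions = c(C_to_BIO = 0.2),
                           iom_mass = 10, process_sd = 0, obs_sd = 0)
  tr <- simulate_process(st, pp, inputs = 0,
                         x0 = c(C = 100, BIO = 0, IOM = 10))
  # survival-fraction oracle: 100 e^-0.1, 0.2 * 100 * (1 - e^-0.1)
  expect_equal(tr$C[2], 100 * exp(-0.1), tolerance = 1e-12)
  expect_equal(tr$BIO[2], 0.2 * 100 * (1 - exp(-0.1)), tolerance = 1e-12)
  expect_equal(tr$IOM[2], 10)
  expect_equal(tr$co2_cum[2], 0.8 * 100 * (1 - exp(-0.1)),
               tolerance = 1e-12)
  expect_equal(round(unlist(tr[2, c("C", "BIO", "IOM")]), 3),
               c(C = 90.484, BIO = 1.903, IOM = 10))
  expect_equal(round(tr$co2_cum[2], 3), 7.613)
})

test_that("zero decay gives identity dynamics and no emission", {
  for (mid in c("one", "two", "three", "five")) {
    st <- build_pool_structure(mid)
    k0 <- setNames(rep(0, length(st$decaying)), st$decaying)
    pp <- default_parameters(st, decay_rates = k0, process_sd = 0)
    sys <- build_linear_system(st, pp)
    expect_equal(unname(sys$A), diag(length(st$pools)), info = mid)
    expect_true(all(sys$co2_frac == 0), info = mid)
    x0 <- setNames(runif(length(st$pools), 5, 20), st$pools)
    if (length(st$constant)) x0[st$constant] <- pp$iom_mass
    tr <- simulate_process(st, pp, inputs = rep(0, 4), x0 = x0)
    expect_equal(unname(as.matrix(tr[, st$pools])),
                 matrix(rep(unname(x0), each = 5), 5), info = mid)
  }
})

test_that("mass balance holds at every noise-free step", {
  set.seed(42)
  for (mid in c("one", "two", "three", "five")) {
    st <- build_pool_structure(mid)
    kk <- setNames(runif(length(st$decaying), 0.01, 1.5), st$decaying)
    pp <- default_parameters(st, decay_rates = kk, process_sd = 0)
    x0 <- setNames(runif(length(st$pools), 2, 40), st$pools)
    if (length(st$constant)) x0[st$constant] <- pp$iom_mass
    inputs <- runif(10, 0, 3)
    tr <- simulate_process(st, pp, inputs, x0)
    emitted <- diff(tr$co2_cum)
    balance <- tr$toc[-11] + inputs - tr$toc[-1] - emitted
    expect_lt(max(abs(balance)) / max(tr$toc), 1e-10)
    if (length(st$constant))
      expect_true(all(tr$IOM == pp$iom_mass), info = mid)
  }
})

test_that("with zero input expected TOC decreases towards the inert mass", {
  st <- build_pool_structure("two")
  pp <- default_parameters(st, decay_rates = c(C = 0.3), iom_mass = 8,
                           process_sd = 0)
  tr <- simulate_process(st, pp, inputs = rep(0, 30),
                         x0 = c(C = 40, IOM = 8))
  expect_true(all(diff(tr$toc) < 0))
  expect_true(all(tr$toc > 8))
  expect_lt(tr$toc[31] - 8, 0.01)
})

test_that("transition matrix is substochastic for any decay rates", {
  set.seed(7)
  for (r in 1:20) {
    mid <- sample(c("one", "two", "three", "five"), 1)
    st <- build_pool_structure(mid)
    kk <- setNames(rexp(length(st$decaying), 0.5), st$decaying)
    pp <- default_parameters(st, decay_rates = kk)
    sys <- build_linear_system(st, pp)
    expect_true(all(sys$A >= 0))
    sr <- max(abs(eigen(sys$A, only.values = TRUE)$values))
    expect_lte(sr, 1 + 1e-12)
    # column totals + CO2 fraction = 1 exactly (mass conservation)
    expect_equal(unname(colSums(sys$A) + sys$co2_frac),
                 rep(1, length(st$pools)), tolerance = 1e-12)
  }
})

test_that("noisy simulation is seeded and centred on the noise-free path", {
  st <- build_pool_structure("three")
  pp <- default_parameters(st, process_sd = 0.5)
  x0 <- c(C = 38, BIO = 1, IOM = 4)
  inputs <- rep(1, 5)
  a <- simulate_process(st, pp, inputs, x0, noise = TRUE, seed = 11)
  b <- simulate_process(st, pp, inputs, x0, noise = TRUE, seed = 11)
  expect_identical(a, b)
  det <- simulate_process(st, pp, inputs, x0)
  n_rep <- 3000
  finals <- replicate(n_rep,
    simulate_process(st, pp, inputs, x0, noise = TRUE)$toc[6])
  se <- sd(finals) / sqrt(n_rep)
  expect_lt(abs(mean(finals) - det$toc[6]), 3 * se)
})

test_that("five-pool input split allocates plant carbon to DPM and RPM", {
  st <- build_pool_structure("five")
  k0 <- setNames(rep(0, 4), st$decaying)
  pp <- default_parameters(st, decay_rates = k0, process_sd = 0)
  x0 <- setNames(c(0, 0, 0, 0, pp$iom_mass), st$pools)
  tr <- simulate_process(st, pp, inputs = 1, x0 = x0)
  expect_equal(tr$DPM[2], 0.59)
  expect_equal(tr$RPM[2], 0.41)
  expect_equal(tr$BIO[2] + tr$HUM[2], 0)
})

test_that("invalid parameters and inputs are rejected", {
  st <- build_pool_structure("three")
  expect_error(default_parameters(st, decay_rates = c(C = -0.1)),
               "nonnegative")
  expect_error(default_parameters(st,
    transfer_fractions = c(BIO_to_BIO = 0.7, BIO_to_C = 0.7)), "exceed 1")
  pp <- default_parameters(st)
  expect_error(simulate_process(st, pp, inputs = -1,
                                x0 = c(C = 10, BIO = 1, IOM = 4)),
               "negative carbon input")
})

test_that("toc sums pool masses", {
  expect_equal(toc(c(C = 90.484, BIO = 1.903, IOM = 10)), 102.387)
  expect_equal(toc(c(C = 0, BIO = 0, IOM = 0)), 0)
  expect_equal(toc(c(C = 33.3)), 33.3)   # one-pool: the single mass
})
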