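# Independent oracles, coded directly from the defining formulas and
# kept free of the package's implementation paths.

# log density of a multivariate normal via Cholesky
dmvnorm_log <- function(x, mu, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# brute-force joint-Gaussian log-likelihood of sparse observations from
# the linear-Gaussian system x[t+1] = A x[t] + b u[t] + w, y = H x + v:
# builds the full joint covariance of the stacked states, then the
# observation moments directly
joint_gaussian_loglik <- function(A, b, Q, H, R, m0, P0, inputs, y, obs_at,
                                  Qt = NULL) {
  p <- nrow(A)
  T_all <- length(inputs) + 1L
  mus <- vector("list", T_all)
  mus[[1]] <- as.numeric(m0)
  for (t in 2:T_all)
    mus[[t]] <- drop(A %*% mus[[t - 1]]) + b * inputs[t - 1]
  # Cov(x_t, x_s): forward recursion on the diagonal, then propagate
  V <- vector("list", T_all)
  V[[1]] <- P0
  for (t in 2:T_all) {
    Qstep <- if (is.null(Qt)) Q else as.matrix(Qt[[t - 1]])
    V[[t]] <- A %*% V[[t - 1]] %*% t(A) + Qstep
  }
  Cov <- function(t, s) {        # t >= s
    M <- V[[s]]
    if (t > s) for (k in seq_len(t - s)) M <- A %*% M
    M
  }
  n <- length(obs_at)
  mu_y <- vapply(obs_at, function(t) drop(H %*% mus[[t]]), numeric(1))
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    t <- obs_at[i]; s <- obs_at[j]
    M <- if (t >= s) Cov(t, s) else t(Cov(s, t))
    S[i, j] <- drop(H %*% M %*% H) + if (i == j) R else 0
  }
  dmvnorm_log(y, mu_y, (S + t(S)) / 2)
}

# classic Gelman-Rubin, coded independently from its defining formula
rhat_ref <- function(xs) {
  m <- length(xs)
  n <- length(xs[[1]])
  means <- sapply(xs, mean)
  W <- mean(sapply(xs, var))
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# random stable linear-Gaussian test system with sparse observations
random_lg_system <- function(p = 2, T_steps = 4, n_obs = 3) {
  A <- matrix(runif(p * p, -0.3, 0.3), p)
  diag(A) <- runif(p, 0.3, 0.9)
  A <- A / max(1.05, max(abs(eigen(A, only.values = TRUE)$values)) * 1.1)
  L <- matrix(rnorm(p * p, sd = 0.5), p)
  Q <- tcrossprod(L) + diag(0.1, p)
  L0 <- matrix(rnorm(p * p, sd = 0.5), p)
  P0 <- tcrossprod(L0) + diag(0.2, p)
  list(A = A, b = runif(p), Q = Q, H = rep(1, p), R = runif(1, 0.2, 1.5),
       m0 = rnorm(p, 10, 2), P0 = P0,
       inputs = runif(T_steps, 0, 2),
       obs_at = sort(sample.int(T_steps + 1L, n_obs)))
}

# simulate observations from a random system (for filter likelihood
# comparisons the y values can be arbitrary, but realistic ones keep
# densities well-scaled)
simulate_lg_obs <- function(sys) {
  p <- length(sys$m0)
  T_all <- length(sys$inputs) + 1L
  x <- sys$m0 + drop(chol(sys$P0) %*% rnorm(p))
  xs <- matrix(NA_real_, p, T_all)
  xs[, 1] <- x
  for (t in 2:T_all) {
    x <- drop(sys$A %*% x) + sys$b * sys$inputs[t - 1] +
      drop(chol(sys$Q) %*% rnorm(p))
    xs[, t] <- x
  }
  vapply(sys$obs_at, function(t)
    sum(xs[, t]) + rnorm(1, 0, sqrt(sys$R)), numeric(1))
}

# Rauch-Tung-Striebel smoother (scalar state), coded directly from the
# standard recursions, for checking posterior state draws
rts_smoother_1d <- function(a, b, q, r, m0, p0, inputs, y, obs_at) {
  T_all <- length(inputs) + 1L
  mf <- pf <- mp <- pp <- numeric(T_all)
  m <- m0; P <- p0
  for (t in seq_len(T_all)) {
    mp[t] <- m; pp[t] <- P
    if (t %in% obs_at) {
      S <- P + r
      K <- P / S
      m <- m + K * (y[match(t, obs_at)] - m)
      P <- (1 - K) * P
    }
    mf[t] <- m; pf[t] <- P
    if (t < T_all) { m <- a * m + b * inputs[t]; P <- a^2 * P + q }
  }
  ms <- mf; Ps <- pf
  for (t in (T_all - 1L):1L) {
    Ppred <- a^2 * pf[t] + q
    J <- pf[t] * a / Ppred
    ms[t] <- mf[t] + J * (ms[t + 1] - (a * mf[t] + b * inputs[t]))
    Ps[t] <- pf[t] + J^2 * (Ps[t + 1] - Ppred)
  }
  list(mean = ms, var = Ps)
}
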