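#' Auxiliary random numbers for a particle filter
#'
#' A fixed-shape block of standard normals (innovations and resampling
#' variates); given the parameters and data it fully determines a
#' filter's likelihood estimate, which is what the correlated
#' pseudo-marginal sampler exploits.  Resampling uniforms are stored as
#' normals and mapped through `pnorm()` at use, so the whole block can
#' be correlated with [correlate_aux()].
#'
#' @param n_particles Number of particles.
#' @param T_len Number of annual steps covered.
#' @param d_innov Innovation dimension per particle-year.
#' @param d_init Initial-state innovation dimension (0 when the initial
#'   state is marginalised exactly).
#' @return An object of class `aux_block`.
#' @export
aux_block <- function(n_particles, T_len, d_innov = 1L, d_init = 0L) {
  structure(list(
    z = array(rnorm(n_particles * T_len * d_innov),
              dim = c(n_particles, T_len, d_innov)),
    z0 = if (d_init > 0) matrix(rnorm(n_particles * d_init),
                                n_particles, d_init) else NULL,
    u = rnorm(T_len)),
    class = "aux_block")
}

#' Correlated refresh of an auxiliary block
#'
#' Proposes `rho * current + sqrt(1 - rho^2) * fresh` standard normals
#' component-wise, the auxiliary move of the correlated pseudo-marginal
#' algorithm; `rho = 0` gives an entirely fresh block (standard
#' pseudo-marginal).
#'
#' @param aux An [aux_block()] (or list of them, refreshed element-wise).
#' @param rho Correlation in `[0, 1)`.
#' @return A new block of the same shape.
#' @export
correlate_aux <- function(aux, rho) {
  if (!inherits(aux, "aux_block"))
    return(lapply(aux, correlate_aux, rho = rho))
  mix <- function(x) {
    if (is.null(x)) return(NULL)
    rho * x + sqrt(1 - rho^2) * array(rnorm(length(x)), dim = dim(x) %||% length(x))
  }
  out <- list(z = mix(aux$z), z0 = mix(aux$z0), u = mix(aux$u))
  class(out) <- "aux_block"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified resampling
#'
#' Draws one index per stratum `((i - 1 + u) / N)` of the cumulative
#' normalised weights.  With equal weights this is exactly the identity
#' permutation.
#'
#' @param weights Nonnegative weights (need not be normalised).
#' @param u Single uniform variate in `[0, 1)`.
#' @return Integer vector of resampled particle indices.
#' @export
stratified_resample <- function(weights, u) {
  n <- length(weights)
  cw <- cumsum(weights) / sum(weights)
  pts <- (seq_len(n) - 1 + u) / n
  findInterval(pts, cw, left.open = TRUE) + 1L
}

logmeanexp <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(lw - m)))
}

#' Bootstrap particle filter for a generic state-space model
#'
#' Propagates particles with the model's own transition (bootstrap
#' proposal), weights them by the observation density where an
#' observation exists, and resamples (stratified) at every weighting
#' step.  Returns the log of the unbiased likelihood estimator; an
#' identical auxiliary block yields an identical estimate.
#'
#' @param model List with elements `T_len`; `init(z0)` returning a
#'   (state-dim x N) particle matrix from the `d_init` initial normals;
#'   `trans(X, t, Z)` advancing particles from year `t` to `t+1` using
#'   the (N x d_innov) innovation normals `Z`; and `obs_loglik(X, t)`
#'   returning per-particle log observation densities at year `t`, or
#'   `NULL` when year `t` is unobserved.
#' @param n_particles Number of particles (>= 1).
#' @param aux An [aux_block()] sized to the model.
#' @return List of class `bpf_result` with `loglik`, per-observation
#'   `obs_loglik` (log mean incremental weights), final `particles` and
#'   effective sample sizes `ess`.
#' @export
bootstrap_pf <- function(model, n_particles, aux) {
  stopifnot(n_particles >= 1, inherits(aux, "aux_block"))
  N <- n_particles
  X <- model$init(aux$z0)
  X <- as.matrix(X)
  loglik <- 0
  obs_ll <- numeric(0)
  ess <- numeric(0)
  for (t in seq_len(model$T_len)) {
    lw <- model$obs_loglik(X, t)
    if (!is.null(lw)) {
      step_ll <- logmeanexp(lw)
      loglik <- loglik + step_ll
      obs_ll <- c(obs_ll, setNames(step_ll, t))
      if (!is.finite(step_ll)) {
        return(structure(list(loglik = -Inf, obs_loglik = obs_ll,
                              particles = X, ess = ess, degenerate = TRUE),
                         class = "bpf_result"))
      }
      w <- exp(lw - max(lw))
      ess <- c(ess, sum(w)^2 / sum(w^2))
      idx <- stratified_resample(w, pnorm(aux$u[t]))
      X <- X[, idx, drop = FALSE]
    }
    if (t < model$T_len)
      X <- model$trans(X, t, matrix(aux$z[, t, ], nrow = N))
  }
  structure(list(loglik = loglik, obs_loglik = obs_ll, particles = X,
                 ess = ess, degenerate = FALSE),
            class = "bpf_result")
}

# initial-state policy for the pool filter: allocate the first observed
# TOC (minus the constant mass) over the decaying pools by fixed shares,
# with a coefficient-of-variation + floor prior spread
filter_control <- function(control = list()) {
  def <- list(x0_shares = NULL, x0_cv = 0.2, x0_sd_floor = 0.5,
              x0_mean = NULL)
  modifyList(def, control)
}

default_x0_shares <- function(structure) {
  switch(structure$model_id,
         one = c(C = 1), two = c(C = 1),
         three = c(C = 0.97, BIO = 0.03),
         five = c(DPM = 0.01, RPM = 0.12, BIO = 0.03, HUM = 0.84))
}

#' Rao-Blackwellised particle filter for a SOC site
#'
#' Particles carry simulated plant-input paths (the nonlinear sub-model,
#' run as a bootstrap filter); conditional on each particle's input path
#' the pool sub-model is linear-Gaussian and is marginalised exactly by
#' the Kalman filter.  Because the Kalman covariance recursion does not
#' depend on the inputs it is shared across particles, so only the
#' per-particle means are propagated.  Weighting and stratified
#' resampling happen at observation years (between observations all
#' normalised weights are equal and stratified resampling is the
#' identity).
#'
#' @param structure,params Pool structure and carbon parameters.
#' @param iparams An [input_params()] object.
#' @param site A [soc_site()].
#' @param n_particles Number of input-path particles.
#' @param aux An [aux_block()] with `T_len = length(site$years)`; if
#'   `NULL` a fresh block is drawn from the current RNG.
#' @param control Filter control list (see details in the vignette):
#'   `x0_shares`, `x0_cv`, `x0_sd_floor`, and `x0_mean` to override the
#'   first-observation-anchored initial mean.
#' @param save_history Keep per-year filtered means/covariances and
#'   ancestry-coherent input paths (needed for state draws)?
#' @param obs_years Optional calendar years: condition only on the
#'   site's observations in these years (used by the cross-validation
#'   folds); default all.
#' @return List of class `rbpf_result` with `loglik`, per-observation
#'   log mean incremental weights `obs_loglik` (named by calendar
#'   year), effective sample sizes, and (with history) the chosen
#'   filter state needed by [draw_trajectory()].
#' @export
rbpf <- function(structure, params, iparams, site, n_particles,
                 aux = NULL, control = list(), save_history = FALSE,
                 obs_years = NULL) {
  stopifnot(inherits(site, "soc_site"), n_particles >= 1)
  ctrl <- filter_control(control)
  N <- as.integer(n_particles)
  T_all <- length(site$years)
  if (is.null(aux)) aux <- aux_block(N, T_all)
  if (dim(aux$z)[1] != N || dim(aux$z)[2] < T_all)
    stop("aux block not sized to this run", call. = FALSE)
  sys <- build_linear_system(structure, params)
  d <- length(sys$decaying_idx)
  A <- sys$A[sys$decaying_idx, sys$decaying_idx, drop = FALSE]
  At <- t(A)
  b <- sys$b[sys$decaying_idx]
  Q <- sys$Q[sys$decaying_idx, sys$decaying_idx, drop = FALSE]
  offset <- sum(sys$const_mass)
  R <- sys$R

  obs <- site$obs
  if (!is.null(obs_years)) obs <- obs[obs$year %in% obs_years, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations to filter", call. = FALSE)
  obs_t <- match(obs$year, site$years)

  # per-particle carbon-input paths for transitions 1..T-1
  crop <- site$treatments %in% .crop_treatments
  cf <- iparams$carbon_content *
    unname(iparams$residue_fraction[site$treatments])
  base <- iparams$yield_coef * site$rain_mm
  U <- matrix(0, N, T_all - 1L)
  cols <- which(crop[seq_len(T_all - 1L)])
  if (length(cols)) {
    zz <- matrix(aux$z[, cols, 1], N)
    U[, cols] <- if (iparams$noise == "lognormal")
      rep(cf[cols] * base[cols], each = N) *
        exp(iparams$input_sd_log * zz)
    else rep(cf[cols], each = N) *
      (rep(base[cols], each = N) + iparams$input_sd_log * zz)
  }

  shares <- ctrl$x0_shares %||% default_x0_shares(structure)
  shares <- shares[structure$decaying]
  m0 <- if (!is.null(ctrl$x0_mean)) rep_len(ctrl$x0_mean, d)
  else pmax(obs$toc[1] - offset, 0.5) * as.numeric(shares)
  nw <- as.numeric(sys$noise_weights)
  P0 <- diag((ctrl$x0_cv * m0 + ctrl$x0_sd_floor * nw)^2, d)

  m <- matrix(m0, d, N)
  P <- P0
  loglik <- 0
  obs_ll <- setNames(rep(NA_real_, nrow(obs)), obs$year)
  ess <- setNames(rep(NA_real_, nrow(obs)), obs$year)
  hist_m <- if (save_history) vector("list", T_all) else NULL
  hist_P <- if (save_history) vector("list", T_all) else NULL
  oi <- 1L
  for (t in seq_len(T_all)) {
    if (oi <= length(obs_t) && obs_t[oi] == t) {
      S <- sum(P) + R
      pred <- colSums(m) + offset
      if (S < 1e-12) {
        lw <- ifelse(abs(obs$toc[oi] - pred) < 1e-6, 0, -Inf)
      } else {
        lw <- dnorm(obs$toc[oi], pred, sqrt(S), log = TRUE)
      }
      step_ll <- logmeanexp(lw)
      obs_ll[oi] <- step_ll
      loglik <- loglik + step_ll
      if (!is.finite(step_ll)) {
        return(structure(list(loglik = -Inf, obs_loglik = obs_ll,
                              ess = ess, degenerate = TRUE),
                         class = "rbpf_result"))
      }
      if (S >= 1e-12) {
        Kg <- rowSums(P) / S
        m <- m + tcrossprod(Kg, obs$toc[oi] - pred)
        P <- P - tcrossprod(Kg) * S
        P <- (P + t(P)) / 2
      }
      w <- exp(lw - max(lw))
      ess[oi] <- sum(w)^2 / sum(w^2)
      idx <- stratified_resample(w, pnorm(aux$u[t]))
      m <- m[, idx, drop = FALSE]
      U <- U[idx, , drop = FALSE]
      if (save_history)
        for (s in seq_len(t - 1L))
          hist_m[[s]] <- hist_m[[s]][, idx, drop = FALSE]
      oi <- oi + 1L
    }
    if (save_history) { hist_m[[t]] <- m; hist_P[[t]] <- P }
    if (t < T_all) {
      m <- A %*% m + tcrossprod(b, U[, t])
      P <- A %*% P %*% At + Q
    }
  }
  structure(list(loglik = loglik, obs_loglik = obs_ll, ess = ess,
                 degenerate = FALSE,
                 history = if (save_history)
                   list(m = hist_m, P = hist_P, U = U, A = A, b = b, Q = Q,
                        offset = offset, pools = sys$pools,
                        decaying_idx = sys$decaying_idx,
                        const_mass = sys$const_mass,
                        years = site$years) else NULL),
            class = "rbpf_result")
}

#' Joint likelihood estimate over the fields of a site
#'
#' Fields share one parameter vector but have independent latent
#' trajectories, so the joint likelihood is the product over fields;
#' each field gets its own auxiliary block.
#'
#' @inheritParams rbpf
#' @param sites A [soc_site()] or list of them.
#' @param aux List of auxiliary blocks, one per field (or `NULL`).
#' @return List with total `loglik` and per-field `rbpf_result`s.
#' @export
soc_loglik <- function(structure, params, iparams, sites, n_particles,
                       aux = NULL, control = list(), save_history = FALSE,
                       obs_years = NULL) {
  sites <- as_site_list(sites)
  if (is.null(aux)) aux <- vector("list", length(sites))
  res <- vector("list", length(sites))
  ll <- 0
  for (i in seq_along(sites)) {
    res[[i]] <- rbpf(structure, params, iparams, sites[[i]], n_particles,
                     aux = aux[[i]], control = control,
                     save_history = save_history, obs_years = obs_years)
    ll <- ll + res[[i]]$loglik
    if (!is.finite(ll)) break
  }
  list(loglik = ll, fields = res)
}

#' Draw one latent trajectory from a filtered field
#'
#' Selects an input-path particle (uniformly, the filter having just
#' resampled at the last observation) and draws the pool trajectory
#' conditional on that path by backward Gaussian (forward-filter
#' backward-sampling) simulation.  Requires an [rbpf()] run with
#' `save_history = TRUE`.
#'
#' @param fit An `rbpf_result` with history.
#' @return Data frame with columns `year`, one per pool, `toc` and
#'   `input` (the particle's carbon-input path).
#' @export
draw_trajectory <- function(fit) {
  h <- fit$history
  if (is.null(h)) stop("rbpf run without save_history", call. = FALSE)
  N <- ncol(h$m[[1]])
  j <- sample.int(N, 1L)
  T_all <- length(h$years)
  kf <- list(filtered_mean = vapply(h$m, function(M) M[, j],
                                    numeric(nrow(h$m[[1]]))),
             filtered_cov = h$P, A = h$A, b = h$b, Q = h$Q, Qt = NULL,
             inputs = h$U[j, ])
  if (is.null(dim(kf$filtered_mean)))
    kf$filtered_mean <- matrix(kf$filtered_mean, 1, T_all)
  Xd <- ffbs_draw(kf)
  p <- length(h$pools)
  X <- matrix(NA_real_, T_all, p, dimnames = list(NULL, h$pools))
  X[, h$decaying_idx] <- t(Xd)
  for (cp in names(h$const_mass)) X[, cp] <- h$const_mass[[cp]]
  cols <- c(list(year = h$years),
            lapply(seq_len(p), function(k) X[, k]),
            list(toc = rowSums(X), input = c(h$U[j, ], NA_real_)))
  names(cols)[2:(p + 1)] <- h$pools
  out <- structure(cols, class = "data.frame",
                   row.names = seq_len(T_all))
  attr(out, "pools") <- h$pools
  out
}
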