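#' Kalman filter for an annual linear-Gaussian system
#'
#' Exact Gaussian marginal log-likelihood and filtered moments for the
#' state-space model `x[t+1] = A x[t] + b u[t] + w[t]`,
#' `w[t] ~ N(0, Q[t])`, with scalar observations `y = H x + v`,
#' `v ~ N(0, R)`, observed only at the years in `obs_at`.  Years without
#' an observation are pure prediction steps.  Degenerate (zero-variance)
#' observations are handled as exact constraints: an innovation larger
#' than a numerical tolerance yields `-Inf` log-likelihood.
#'
#' @param A Square transition matrix (destination x source).
#' @param b Input allocation vector.
#' @param Q Process noise covariance; use `Qt` (list, one matrix per
#'   transition) when time-varying.
#' @param H Observation row vector.
#' @param R Observation variance (scalar).
#' @param m0,P0 Prior mean and covariance of the state in year 1.
#' @param inputs Annual inputs `u[t]`, `t = 1..T-1`, driving transitions;
#'   the filter covers years `1..length(inputs)+1`.
#' @param y Observed values, one per entry of `obs_at`.
#' @param obs_at Integer years (in `1..T`) carrying an observation.
#' @param Qt Optional list of per-transition process covariances.
#' @return List of class `kf_result`: `loglik`, matrices
#'   `filtered_mean` (p x T), lists `filtered_cov`, per-observation
#'   log predictive contributions `obs_loglik` (named by year), and the
#'   inputs used (for smoothing).
#' @export
#' @examples
#' kalman_filter(A = matrix(1), b = 0, Q = matrix(0), H = 1, R = 1,
#'               m0 = 0, P0 = matrix(0), inputs = numeric(),
#'               y = 0, obs_at = 1)$loglik  # -log(sqrt(2*pi))
kalman_filter <- function(A, b, Q, H, R, m0, P0, inputs, y, obs_at,
                          Qt = NULL) {
  A <- as.matrix(A); Q <- as.matrix(Q); P0 <- as.matrix(P0)
  p <- nrow(A)
  T_all <- length(inputs) + 1L
  if (length(y) != length(obs_at))
    stop("y and obs_at lengths differ", call. = FALSE)
  if (length(obs_at) && (min(obs_at) < 1 || max(obs_at) > T_all))
    stop("observation years outside trajectory", call. = FALSE)
  check_psd <- function(M, what) {
    M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8 * max(1, abs(ev[1]))))
      stop(what, " is not positive semi-definite", call. = FALSE)
    M
  }
  P <- check_psd(P0, "initial covariance")
  if (is.null(Qt)) Q <- check_psd(Q, "process covariance")
  if (R < 0) stop("observation variance must be nonnegative", call. = FALSE)
  m <- as.numeric(m0)
  fm <- matrix(NA_real_, p, T_all)
  fc <- vector("list", T_all)
  obs_ll <- setNames(rep(NA_real_, length(obs_at)), obs_at)
  loglik <- 0
  oi <- 1L
  for (t in seq_len(T_all)) {
    if (oi <= length(obs_at) && obs_at[oi] == t) {
      S <- drop(H %*% P %*% H) + R
      innov <- y[oi] - drop(H %*% m)
      if (S < 1e-12) {
        ll <- if (abs(innov) < 1e-6) 0 else -Inf
      } else {
        ll <- dnorm(innov, 0, sqrt(S), log = TRUE)
        K <- drop(P %*% H) / S
        m <- m + K * innov
        P <- P - tcrossprod(K) * S
        P <- (P + t(P)) / 2
      }
      loglik <- loglik + ll
      obs_ll[oi] <- ll
      oi <- oi + 1L
    }
    fm[, t] <- m
    fc[[t]] <- P
    if (t < T_all) {
      m <- drop(A %*% m) + b * inputs[t]
      Qstep <- if (is.null(Qt)) Q else as.matrix(Qt[[t]])
      P <- A %*% P %*% t(A) + Qstep
      P <- (P + t(P)) / 2
    }
  }
  structure(list(loglik = loglik, filtered_mean = fm, filtered_cov = fc,
                 obs_loglik = obs_ll, A = A, b = b, Q = Q, Qt = Qt,
                 inputs = inputs),
            class = "kf_result")
}

# draw one state trajectory from p(x_{1:T} | y) by backward (FFBS)
# sampling, given filtered moments.  The fast path assumes positive
# definite predictive covariances (Cholesky); any failure falls back to
# a pseudo-inverse pass that handles zero-noise degeneracy (where the
# draw collapses to the smoother mean).
ffbs_draw <- function(kf) {
  tryCatch(ffbs_core(kf, robust = FALSE),
           error = function(e) ffbs_core(kf, robust = TRUE))
}

ffbs_core <- function(kf, robust) {
  p <- nrow(kf$filtered_mean)
  T_all <- ncol(kf$filtered_mean)
  X <- matrix(NA_real_, p, T_all)
  X[, T_all] <- rmvnorm1(kf$filtered_mean[, T_all],
                         kf$filtered_cov[[T_all]], robust)
  if (T_all == 1L) return(X)
  At <- t(kf$A)
  for (t in (T_all - 1L):1L) {
    Pt <- kf$filtered_cov[[t]]
    Qstep <- if (is.null(kf$Qt)) kf$Q else as.matrix(kf$Qt[[t]])
    Ppred <- kf$A %*% Pt %*% At + Qstep
    PAt <- Pt %*% At
    J <- if (robust)
      t(MASS::ginv((Ppred + t(Ppred)) / 2) %*% t(PAt))
    else PAt %*% chol2inv(chol(Ppred))
    mpred <- drop(kf$A %*% kf$filtered_mean[, t]) + kf$b * kf$inputs[t]
    mu <- kf$filtered_mean[, t] + drop(J %*% (X[, t + 1] - mpred))
    Sig <- Pt - J %*% t(PAt)
    X[, t] <- rmvnorm1(mu, Sig, robust)
  }
  X
}

# one multivariate normal draw; the robust mode tolerates rank-deficient
# covariance via an eigen square root
rmvnorm1 <- function(mu, Sigma, robust = TRUE) {
  Sigma <- as.matrix(Sigma)
  if (all(abs(Sigma) < 1e-14)) return(as.numeric(mu))
  Sigma <- (Sigma + t(Sigma)) / 2
  if (!robust)
    return(as.numeric(mu + crossprod(chol(Sigma), rnorm(length(mu)))))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (!is.null(ch))
    return(as.numeric(mu + crossprod(ch, rnorm(length(mu)))))
  eg <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  as.numeric(mu + eg$vectors %*% (sqrt(ev) * rnorm(length(mu))))
}
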