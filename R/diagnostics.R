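#' Posterior SOC change since the first trial year
#'
#' The change functional is `g = TOC(t) - TOC(1)` for each posterior
#' trajectory draw; its Monte-Carlo mean is the Bayes estimate of the
#' SOC change of the field, the (n-1)-denominator sample variance its
#' uncertainty, and the empirical percentiles give credible limits.
#' Negative values denote expected carbon loss since the first year.
#'
#' @param toc_mat Draws x years matrix of TOC trajectories (see
#'   [toc_draws()]).
#' @param t Optional year indices (1-based within the trial) to report;
#'   default all years.
#' @return Data frame with columns `year`, `mean_change`, `var_change`,
#'   `p2.5`, `p97.5`; the reference year has change identically 0.
#' @export
#' @examples
#' m <- rbind(c(100, 95), c(100, 105))
#' soc_change(m)   # year 2: mean 0, var 50
soc_change <- function(toc_mat, t = NULL) {
  toc_mat <- as.matrix(toc_mat)
  if (nrow(toc_mat) < 1) stop("no posterior draws", call. = FALSE)
  T_all <- ncol(toc_mat)
  if (is.null(t)) t <- seq_len(T_all)
  if (any(t < 1 | t > T_all))
    stop("year index out of range 1..", T_all, call. = FALSE)
  g <- toc_mat[, t, drop = FALSE] - toc_mat[, 1]
  yrs <- colnames(toc_mat)[t] %||% as.character(t)
  data.frame(year = as.integer(yrs),
             mean_change = colMeans(g),
             var_change = apply(g, 2, var),
             p2.5 = apply(g, 2, quantile, probs = 0.025, names = FALSE),
             p97.5 = apply(g, 2, quantile, probs = 0.975, names = FALSE),
             row.names = NULL)
}

#' Posterior credible band of the SOC trajectory
#'
#' Empirical per-year percentiles of TOC across posterior draws; the
#' defaults give the 95% band (2.5/97.5), the interquartile band and
#' the median.
#'
#' @param toc_mat Draws x years matrix (see [toc_draws()]).
#' @param probs Percentile probabilities in (0, 1).
#' @return Data frame with `year` and one `p<100q>` column per
#'   probability.
#' @export
credible_band <- function(toc_mat,
                          probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  toc_mat <- as.matrix(toc_mat)
  if (nrow(toc_mat) < 1) stop("no posterior draws", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  qs <- apply(toc_mat, 2, quantile, probs = probs, names = FALSE)
  qs <- matrix(qs, nrow = length(probs))
  out <- data.frame(year = as.integer(colnames(toc_mat) %||%
                                        seq_len(ncol(toc_mat))),
                    t(qs), row.names = NULL)
  names(out)[-1] <- paste0("p", formatC(100 * probs, format = "g"))
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) diagnostic comparing between- and within-chain
#' variances; values below 1.2 are taken as no evidence of
#' non-convergence.  `split = TRUE` halves each chain first (split-Rhat
#' variant).
#'
#' @param chains A [cpm_mcmc()] trace, a list of equal-length numeric
#'   vectors (one parameter), or a list of draw matrices with matching
#'   columns.
#' @param split Use the split-chain variant? Default `FALSE`.
#' @param threshold Convergence flag threshold, default 1.2.
#' @return Data frame with columns `parameter`, `rhat`, `converged`.
#' @export
#' @examples
#' gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))  # rhat = sqrt(0.75)
gelman_rubin <- function(chains, split = FALSE, threshold = 1.2) {
  if (inherits(chains, "soc_trace"))
    chains <- retained_draws(chains, pooled = FALSE)
  if (!is.matrix(chains[[1]]))
    chains <- lapply(chains, function(x) matrix(x, ncol = 1,
                                                dimnames = list(NULL, "x")))
  if (length(chains) < 2)
    stop("at least two chains are required", call. = FALSE)
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  if (n < 2) stop("chains must have length at least 2", call. = FALSE)
  if (split) {
    h <- n %/% 2
    chains <- c(lapply(chains, function(m) m[seq_len(h), , drop = FALSE]),
                lapply(chains, function(m) m[(n - h + 1):n, , drop = FALSE]))
    n <- h
  }
  pn <- colnames(chains[[1]])
  rhat <- vapply(seq_along(pn), function(j) {
    xs <- lapply(chains, function(m) m[, j])
    W <- mean(vapply(xs, var, numeric(1)))
    B_over_n <- var(vapply(xs, mean, numeric(1)))
    if (W < .Machine$double.eps) return(1)
    sqrt((n - 1) / n + B_over_n / W)
  }, numeric(1))
  data.frame(parameter = pn, rhat = rhat, converged = rhat < threshold,
             row.names = NULL)
}
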