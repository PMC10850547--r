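#' One-step-ahead posterior predictive density
#'
#' Monte-Carlo estimate of `p(Y[t+1] | Y[1:t])`: for each retained
#' posterior draw (fitted on the history), the Rao-Blackwellised filter
#' is run conditioned on the history observations and extended through
#' the (possibly multi-year) gap to the next observation event; the
#' incremental mean weight at that event is the conditional predictive
#' density for that draw, and the estimator averages over draws.  Fields
#' observed in the same year contribute jointly (product over fields).
#'
#' @param trace A [cpm_mcmc()] trace fitted to the history
#'   observations.
#' @param structure,sites,base_params,base_iparams,control As in
#'   [cpm_mcmc()].
#' @param history_upto Calendar year: observations up to and including
#'   this year form the conditioning history.
#' @param next_year Calendar year of the predicted observation event.
#' @param n_particles Particles per filter run.
#' @param seed Integer seed for the fresh auxiliary draws.
#' @param max_draws Optional cap on the posterior draws used.
#' @return List with the density estimate `mean`, its Monte-Carlo
#'   standard error `se`, and the per-draw densities.
#' @export
predictive_density <- function(trace, structure, sites, history_upto,
                               next_year, n_particles = NULL,
                               base_params = NULL,
                               base_iparams = input_params(),
                               control = list(), seed = 1,
                               max_draws = NULL) {
  sites <- as_site_list(sites)
  if (is.null(base_params)) base_params <- default_parameters(structure)
  if (is.null(n_particles)) n_particles <- trace$config$n_particles
  th_mat <- retained_draws(trace)
  if (nrow(th_mat) == 0) stop("need at least one posterior draw",
                              call. = FALSE)
  if (!is.null(max_draws) && nrow(th_mat) > max_draws)
    th_mat <- th_mat[round(seq(1, nrow(th_mat), length.out = max_draws)), ,
                     drop = FALSE]
  # fields with an observation at the predicted event
  pred_fields <- which(vapply(sites, function(s)
    next_year %in% s$obs$year, logical(1)))
  if (!length(pred_fields))
    stop("no field observed in year ", next_year, call. = FALSE)
  set.seed(seed)
  lpd <- numeric(nrow(th_mat))
  for (m in seq_len(nrow(th_mat))) {
    pp <- apply_theta(structure, base_params, base_iparams, th_mat[m, ])
    if (is.null(pp)) { lpd[m] <- -Inf; next }
    acc <- 0
    for (i in pred_fields) {
      s <- sites[[i]]
      cond_years <- c(s$obs$year[s$obs$year <= history_upto], next_year)
      fit <- rbpf(structure, pp$params, pp$iparams, s, n_particles,
                  control = control, obs_years = cond_years)
      acc <- acc + fit$obs_loglik[[as.character(next_year)]]
    }
    lpd[m] <- acc
  }
  pd <- exp(lpd)
  list(mean = mean(pd), se = sd(pd) / sqrt(length(pd)), per_draw = pd)
}

#' Leave-future-out cross-validation of a SOC model
#'
#' Folds are indexed by observation events (calendar years in which any
#' field has a measurement).  For each fold `t` in `L, ..., T-1` the
#' model is refitted by [cpm_mcmc()] to the first `t` events only, the
#' predictive density of event `t+1` is estimated by
#' [predictive_density()], and the expected log pointwise predictive
#' density (ELPD) accumulates the log predictive densities over folds.
#'
#' @param structure A [build_pool_structure()] object.
#' @param sites Field series (shared folds across fields).
#' @param priors Sampled-parameter priors.
#' @param L Minimum number of observation events required before
#'   predicting; must be smaller than the number of events.
#' @param config MCMC configuration for the per-fold refits.
#' @param base_params,base_iparams,control,proposal_scales As in
#'   [cpm_mcmc()].
#' @param n_particles_pred Particles for the predictive runs (default:
#'   the fit configuration's).
#' @param max_pred_draws Optional cap on posterior draws per fold.
#' @param verbose Print fold progress?
#' @return An object of class `elpd_result` with `model_id`, `L`,
#'   per-fold table (`year`, `log_pred`, `se_log`), `elpd_total` and
#'   the combined Monte-Carlo standard error `mc_se`.
#' @export
lfo_cv <- function(structure, sites, priors, L,
                   config = soc_mcmc_config(), base_params = NULL,
                   base_iparams = input_params(), control = list(),
                   proposal_scales = NULL, n_particles_pred = NULL,
                   max_pred_draws = NULL, verbose = FALSE) {
  sites <- as_site_list(sites)
  events <- obs_events(sites)
  T_ev <- length(events)
  if (L >= T_ev)
    stop("L (", L, ") must be smaller than the number of observation ",
         "events (", T_ev, "): too few observations to predict from",
         call. = FALSE)
  if (L < 1) stop("L must be at least 1", call. = FALSE)
  folds <- L:(T_ev - 1L)
  log_pred <- se_log <- numeric(length(folds))
  for (k in seq_along(folds)) {
    t <- folds[k]
    cutoff <- events[t]
    nxt <- events[t + 1L]
    sites_t <- lapply(sites, truncate_obs, cutoff_year = cutoff)
    sites_t <- sites_t[vapply(sites_t, function(s) nrow(s$obs) > 0,
                              logical(1))]
    cfg <- config
    cfg$seed <- config$seed + 7919L * k
    cfg$store_states <- FALSE   # fold refits only need the theta draws
    trace <- cpm_mcmc(structure, sites_t, priors, cfg,
                      base_params = base_params,
                      base_iparams = base_iparams, control = control,
                      proposal_scales = proposal_scales)
    pd <- predictive_density(trace, structure, sites, cutoff, nxt,
                             n_particles = n_particles_pred %||%
                               config$n_particles,
                             base_params = base_params,
                             base_iparams = base_iparams,
                             control = control,
                             seed = cfg$seed + 1L,
                             max_draws = max_pred_draws)
    log_pred[k] <- log(pd$mean)
    se_log[k] <- pd$se / pd$mean   # delta method on the log scale
    if (verbose)
      message(sprintf("fold %d/%d (predict %d): log p = %.3f",
                      k, length(folds), nxt, log_pred[k]))
  }
  structure(list(model_id = structure$model_id, L = L,
                 folds = data.frame(year = events[folds + 1L],
                                    log_pred = log_pred,
                                    se_log = se_log),
                 elpd_total = sum(log_pred),
                 mc_se = sqrt(sum(se_log^2))),
            class = "elpd_result")
}

#' @export
print.elpd_result <- function(x, ...) {
  cat(x$model_id, "-pool model: ELPD = ", sprintf("%.2f", x$elpd_total),
      " (MC se ", sprintf("%.3f", x$mc_se), ", L = ", x$L, ", ",
      nrow(x$folds), " folds)\n", sep = "")
  invisible(x)
}

#' Rank candidate models by ELPD
#'
#' Orders [lfo_cv()] results by decreasing ELPD (computed on identical
#' folds) and flags models whose ELPD lies within twice the combined
#' Monte-Carlo standard error of the best model as statistically
#' indistinguishable from it.
#'
#' @param results List of `elpd_result` objects.
#' @return Data frame with columns `model_id`, `elpd`, `mc_se`, `rank`
#'   and `indistinguishable_from_best`.
#' @export
rank_models <- function(results) {
  if (inherits(results, "elpd_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "elpd_result")))
  if (length(results) > 1) {
    folds <- lapply(results, function(r) r$folds$year)
    if (!all(vapply(folds, identical, logical(1), folds[[1]])))
      stop("results were computed on different fold sets", call. = FALSE)
  }
  df <- data.frame(
    model_id = vapply(results, `[[`, character(1), "model_id"),
    elpd = vapply(results, `[[`, numeric(1), "elpd_total"),
    mc_se = vapply(results, `[[`, numeric(1), "mc_se"))
  df <- df[order(-df$elpd), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  best <- df[1, ]
  df$indistinguishable_from_best <- c(FALSE,
    abs(df$elpd[-1] - best$elpd) <
      2 * sqrt(df$mc_se[-1]^2 + best$mc_se^2))[seq_len(nrow(df))]
  rownames(df) <- NULL
  df
}
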