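#' Microbial biomass cap check
#'
#' TRUE iff the BIO pool mass is at most `cap` times TOC in every year
#' of the trajectory (boundary inclusive).  Trajectories from structures
#' without a BIO pool satisfy the constraint vacuously (with a warning).
#'
#' @param trajectory Data frame with a `BIO` and a `toc` column (as
#'   produced by [draw_trajectory()] or [simulate_process()]).
#' @param cap Maximum BIO share of TOC; default 0.05.
#' @return Logical scalar.
#' @export
#' @examples
#' tr <- data.frame(year = 1:2, BIO = c(1, 2), toc = c(30, 30))
#' check_bio_constraint(tr)
check_bio_constraint <- function(trajectory, cap = 0.05) {
  if (!"BIO" %in% names(trajectory)) {
    warning("structure has no BIO pool; constraint vacuously true")
    return(TRUE)
  }
  all(trajectory$BIO <= cap * trajectory$toc)
}

#' MCMC run configuration
#'
#' Defaults follow the reference workflow: 4 chains of 200,000
#' iterations, 80,000 burn-in, thinning every 30th sample (4,000
#' retained draws per chain), auxiliary-variable correlation 0.99.
#' Scale these down for exploratory runs.
#'
#' @param iterations,burn_in,thin,n_chains Chain geometry.
#' @param n_particles Particles in each likelihood estimate.
#' @param rho Auxiliary correlation in `[0, 1)`; 0 gives the standard
#'   (uncorrelated) pseudo-marginal sampler.
#' @param seed Integer seed; chain `c` uses `seed + (c-1) * 100003`.
#' @param bio_cap Microbial biomass cap as a share of TOC.
#' @param store_states Store a state trajectory per retained draw
#'   (default); disable to cheapen runs where only the parameter
#'   posterior is needed (e.g. cross-validation refits).
#' @return A validated config list.
#' @export
soc_mcmc_config <- function(iterations = 200000, burn_in = 80000,
                            thin = 30, n_chains = 4, n_particles = 100,
                            rho = 0.99, seed = 1, bio_cap = 0.05,
                            store_states = TRUE) {
  if (burn_in >= iterations)
    stop("burn_in must be smaller than iterations", call. = FALSE)
  if (thin < 1) stop("thin must be at least 1", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (n_chains < 1 || n_particles < 1)
    stop("need at least one chain and one particle", call. = FALSE)
  list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
       thin = as.integer(thin), n_chains = as.integer(n_chains),
       n_particles = as.integer(n_particles), rho = rho,
       seed = as.integer(seed), bio_cap = bio_cap,
       store_states = isTRUE(store_states))
}

# patch a (params, iparams) pair with sampled values; returns NULL when
# the proposal is inadmissible (route fractions of a source exceeding 1,
# negative masses/scales under an unbounded prior)
apply_theta <- function(structure, params, iparams, theta) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (startsWith(nm, "K_")) {
      params$decay_rates[[substring(nm, 3)]] <- v
    } else if (grepl("_to_", nm, fixed = TRUE) || startsWith(nm, "split_")) {
      if (v < 0 || v > 1) return(NULL)
      params$transfer_fractions[[nm]] <- v
    } else if (nm %in% c("iom_mass", "process_sd", "obs_sd")) {
      if (v < 0) return(NULL)
      params[[nm]] <- v
    } else if (nm %in% c("yield_coef", "input_sd_log", "carbon_content")) {
      if (v < 0) return(NULL)
      iparams[[nm]] <- v
    } else stop("unknown parameter name: ", nm, call. = FALSE)
  }
  for (src in names(structure$routes)) {
    pars <- unlist(structure$routes[[src]])
    if (length(pars) &&
        sum(params$transfer_fractions[pars]) > 1 + 1e-12) return(NULL)
  }
  list(params = params, iparams = iparams)
}

#' Correlated pseudo-marginal MCMC for a SOC model
#'
#' Metropolis-Hastings over the sampled parameters (those named in
#' `priors`), with the intractable likelihood replaced by the
#' Rao-Blackwellised particle filter estimate and the auxiliary random
#' numbers of consecutive estimates correlated (`rho`).  Proposals are
#' independent Gaussian random walks on the prior-driven unconstrained
#' scale (log / logit / identity), with the transform Jacobian in the
#' target.  For structures with a BIO pool, a state trajectory is drawn
#' for every Metropolis-accepted proposal and the proposal is rejected
#' if the trajectory exceeds the microbial cap in any year.
#'
#' @param structure A [build_pool_structure()] object.
#' @param sites A [soc_site()] or list of fields sharing the parameters.
#' @param priors A [prior_set()] naming the sampled parameters.
#' @param config A [soc_mcmc_config()].
#' @param base_params,base_iparams Baseline parameter objects supplying
#'   the non-sampled values; defaults [default_parameters()] /
#'   [input_params()].
#' @param proposal_scales Named vector of random-walk sds on the
#'   unconstrained scale (default 0.25 each, giving roughly 20-40%
#'   acceptance on the bundled synthetic worlds).
#' @param control Filter control passed to [rbpf()].
#' @param init Optional named vector of starting values (default: drawn
#'   from the priors).
#' @param verbose Print per-chain progress?
#' @return An object of class `soc_trace`: per chain the retained draw
#'   matrix, log-likelihood estimates, stored state trajectories (one
#'   per retained draw, per field) and acceptance rate.
#' @export
cpm_mcmc <- function(structure, sites, priors, config = soc_mcmc_config(),
                     base_params = NULL, base_iparams = input_params(),
                     proposal_scales = NULL, control = list(),
                     init = NULL, verbose = FALSE) {
  sites <- as_site_list(sites)
  stopifnot(inherits(priors, "prior_set"))
  if (is.null(base_params)) base_params <- default_parameters(structure)
  pn <- names(priors)
  d <- length(pn)
  scales <- setNames(rep(0.25, d), pn)
  if (!is.null(proposal_scales))
    scales[names(proposal_scales)] <- proposal_scales
  n_ret <- (config$iterations - config$burn_in) %/% config$thin
  has_bio <- "BIO" %in% structure$pools
  T_lens <- vapply(sites, function(s) length(s$years), integer(1))

  to_unc <- function(th) vapply(pn, function(nm)
    prior_to_unc(priors[[nm]], th[[nm]]), numeric(1))
  from_unc <- function(phi) setNames(vapply(pn, function(nm)
    prior_from_unc(priors[[nm]], phi[[nm]]), numeric(1)), pn)
  log_target_prior <- function(th, phi) {
    lp <- log_prior(th, priors)
    lj <- sum(vapply(pn, function(nm)
      prior_log_jac(priors[[nm]], phi[[nm]]), numeric(1)))
    lp + lj
  }
  eval_loglik <- function(th, aux, save_history = FALSE) {
    pp <- apply_theta(structure, base_params, base_iparams, th)
    if (is.null(pp)) return(NULL)
    soc_loglik(structure, pp$params, pp$iparams, sites,
               config$n_particles, aux = aux, control = control,
               save_history = save_history)
  }
  draw_trajs <- function(fit) lapply(fit$fields, draw_trajectory)
  trajs_ok <- function(trajs) {
    !has_bio || all(vapply(trajs, function(tr)
      all(tr$BIO <= config$bio_cap * tr$toc), logical(1)))
  }

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + (ch - 1L) * 100003L)
    # initialise at an admissible point with an admissible trajectory
    ok <- FALSE
    for (try in 1:200) {
      th <- if (!is.null(init)) unlist(init)[pn] else
        setNames(vapply(pn, function(nm) prior_sample(priors[[nm]]),
                        numeric(1)), pn)
      aux <- lapply(T_lens, function(Tl) aux_block(config$n_particles, Tl))
      fit <- eval_loglik(th, aux, save_history = has_bio)
      if (is.null(fit) || !is.finite(fit$loglik)) next
      trajs <- if (has_bio) draw_trajs(fit) else NULL
      if (has_bio && !trajs_ok(trajs)) next
      ok <- TRUE; break
    }
    if (!ok) stop("could not find an admissible starting point; ",
                  "check priors/init against the BIO constraint",
                  call. = FALSE)
    phi <- to_unc(th)
    cur_ll <- fit$loglik
    cur_lp <- log_target_prior(th, phi)
    cur_trajs <- trajs

    draws <- matrix(NA_real_, n_ret, d, dimnames = list(NULL, pn))
    lls <- numeric(n_ret)
    traj_store <- vector("list", n_ret)
    n_acc <- 0L
    ri <- 0L
    for (i in seq_len(config$iterations)) {
      phi_p <- phi + scales * rnorm(d)
      aux_p <- correlate_aux(aux, config$rho)
      th_p <- from_unc(phi_p)
      lp_p <- log_target_prior(th_p, phi_p)
      accept <- FALSE
      if (is.finite(lp_p)) {
        fit_p <- eval_loglik(th_p, aux_p, save_history = has_bio)
        if (!is.null(fit_p) && is.finite(fit_p$loglik)) {
          la <- (fit_p$loglik + lp_p) - (cur_ll + cur_lp)
          if (log(runif(1)) < la) {
            if (has_bio) {
              # draw the trajectory checked against the microbial cap
              trajs_p <- draw_trajs(fit_p)
              if (trajs_ok(trajs_p)) {
                th <- th_p; phi <- phi_p; aux <- aux_p
                cur_ll <- fit_p$loglik; cur_lp <- lp_p
                cur_trajs <- trajs_p
                accept <- TRUE
              }
            } else {
              th <- th_p; phi <- phi_p; aux <- aux_p
              cur_ll <- fit_p$loglik; cur_lp <- lp_p
              cur_trajs <- NULL   # drawn lazily at retention
              accept <- TRUE
            }
          }
        }
      }
      if (accept) n_acc <- n_acc + 1L
      if (i > config$burn_in && (i - config$burn_in) %% config$thin == 0L) {
        ri <- ri + 1L
        draws[ri, ] <- th
        lls[ri] <- cur_ll
        if (is.null(cur_trajs) && config$store_states)
          cur_trajs <- draw_trajs(eval_loglik(th, aux, save_history = TRUE))
        traj_store[[ri]] <- cur_trajs
      }
    }
    chains[[ch]] <- list(draws = draws, loglik = lls,
                         trajectories = traj_store,
                         accept_rate = n_acc / config$iterations,
                         seed = config$seed + (ch - 1L) * 100003L)
    if (verbose)
      message(sprintf("chain %d/%d: acceptance %.1f%%", ch,
                      config$n_chains, 100 * n_acc / config$iterations))
  }
  structure(list(chains = chains, param_names = pn, config = config,
                 model_id = structure$model_id, priors = priors),
            class = "soc_trace")
}

#' @export
print.soc_trace <- function(x, ...) {
  n_ret <- nrow(x$chains[[1]]$draws)
  cat("CPM trace: ", x$model_id, "-pool model, ", length(x$chains),
      " chain(s) x ", n_ret, " retained draws\n", sep = "")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  cat("  acceptance:", paste(sprintf("%.1f%%",
      100 * vapply(x$chains, `[[`, numeric(1), "accept_rate")),
      collapse = ", "), "\n")
  invisible(x)
}

#' Pooled retained draws of a trace
#'
#' @param trace A `soc_trace`.
#' @param pooled Pool chains into one matrix (default) or return a list
#'   of per-chain matrices.
#' @return Matrix (draws x parameters) or list of matrices.
#' @export
retained_draws <- function(trace, pooled = TRUE) {
  ms <- lapply(trace$chains, `[[`, "draws")
  if (pooled) do.call(rbind, ms) else ms
}

#' Posterior state trajectories for retained draws
#'
#' For each retained parameter draw, re-runs the Rao-Blackwellised
#' filter with fresh auxiliary variables and draws one state trajectory
#' per field (particle input path + backward Gaussian pool draw).  For
#' structures with a BIO pool, draws violating the microbial cap are
#' rejected and redrawn (up to `max_tries`).
#'
#' @param trace A [cpm_mcmc()] trace.
#' @param structure,sites,base_params,base_iparams,control As in
#'   [cpm_mcmc()].
#' @param n_particles Particles per filter run (default from the trace
#'   config).
#' @param seed Integer seed.
#' @param max_draws Optional cap on the number of retained draws used
#'   (evenly thinned), to bound cost.
#' @param max_tries Rejection retries per draw under the BIO cap.
#' @return An object of class `soc_state_draws`: per field a list of
#'   trajectory data frames, plus `years` and `pools`.
#' @export
sample_posterior_states <- function(trace, structure, sites,
                                    base_params = NULL,
                                    base_iparams = input_params(),
                                    n_particles = NULL, seed = 1,
                                    control = list(), max_draws = NULL,
                                    max_tries = 100) {
  sites <- as_site_list(sites)
  if (is.null(base_params)) base_params <- default_parameters(structure)
  if (is.null(n_particles)) n_particles <- trace$config$n_particles
  th_mat <- retained_draws(trace)
  if (nrow(th_mat) == 0) stop("trace has no retained draws", call. = FALSE)
  if (!is.null(max_draws) && nrow(th_mat) > max_draws)
    th_mat <- th_mat[round(seq(1, nrow(th_mat), length.out = max_draws)), ,
                     drop = FALSE]
  has_bio <- "BIO" %in% structure$pools
  cap <- trace$config$bio_cap %||% 0.05
  set.seed(seed)
  out <- lapply(sites, function(s) vector("list", nrow(th_mat)))
  for (m in seq_len(nrow(th_mat))) {
    th <- th_mat[m, ]
    pp <- apply_theta(structure, base_params, base_iparams, th)
    if (is.null(pp)) stop("retained draw is inadmissible", call. = FALSE)
    for (i in seq_along(sites)) {
      for (try in seq_len(max_tries)) {
        fit <- rbpf(structure, pp$params, pp$iparams, sites[[i]],
                    n_particles, control = control, save_history = TRUE)
        tr <- draw_trajectory(fit)
        if (!has_bio || all(tr$BIO <= cap * tr$toc)) break
        tr <- NULL
      }
      if (is.null(tr))
        stop("could not draw a trajectory satisfying the BIO cap",
             call. = FALSE)
      out[[i]][[m]] <- tr
    }
  }
  structure(list(fields = out,
                 field_ids = vapply(sites, function(s)
                   as.character(s$field_id), character(1)),
                 years = lapply(sites, `[[`, "years"),
                 pools = structure$pools),
            class = "soc_state_draws")
}

#' TOC draw matrix for one field
#'
#' Stacks the total-organic-carbon series of each posterior trajectory
#' draw into a draws x years matrix (input for [soc_change()] and
#' [credible_band()]).
#'
#' @param draws A `soc_state_draws` object, or a trace produced by
#'   [cpm_mcmc()] (whose stored acceptance-time trajectories are used).
#' @param field Field index (position in the site list).
#' @return Numeric matrix, columns named by calendar year.
#' @export
toc_draws <- function(draws, field = 1L) {
  if (inherits(draws, "soc_trace")) {
    trs <- unlist(lapply(draws$chains, function(ch)
      lapply(ch$trajectories, `[[`, field)), recursive = FALSE)
    if (any(vapply(trs, is.null, logical(1))))
      stop("trace holds no state trajectories (run with store_states ",
           "= TRUE, or use sample_posterior_states())", call. = FALSE)
  } else if (inherits(draws, "soc_state_draws")) {
    trs <- draws$fields[[field]]
  } else stop("unsupported draws object", call. = FALSE)
  out <- t(vapply(trs, `[[`, numeric(nrow(trs[[1]])), "toc"))
  colnames(out) <- trs[[1]]$year
  out
}
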