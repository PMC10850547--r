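#' Configuration of a synthetic trial site
#'
#' Describes a complete synthetic world: trial years, per-field
#' management templates, a Gamma rainfall regime, sparse observation
#' years, the generating pool model and its true parameters.  Defaults
#' give realistic magnitudes for a long-term Australian cereal trial
#' (initial TOC around 45 Mg C/ha, IOM around 10% of it).
#'
#' @param n_fields Number of fields (independent latent trajectories).
#' @param years Consecutive calendar years of the trial.
#' @param treatments List (length `n_fields`) of per-year treatment
#'   label vectors, or a single vector recycled to all fields.
#' @param obs_years List (length `n_fields`) of observation years, or a
#'   single vector recycled; at least 2 per field, within the trial.
#' @param rain_mean,rain_shape Gamma rainfall regime: mean growing-season
#'   rainfall (mm) and shape (dispersion; CV = `1/sqrt(shape)`).
#' @param model_id Generating pool topology.
#' @param params True carbon parameters (default
#'   [default_parameters()]).
#' @param iparams True input parameters (default [input_params()]).
#' @param x0_toc Initial total SOC, Mg C/ha.
#' @param x0_shares Allocation of the initial decomposable mass over
#'   decaying pools (default as in the filter).
#' @param seed Integer seed.
#' @return An object of class `site_config`.
#' @export
site_config <- function(n_fields = 3, years = 1979:1997,
                        treatments = "wheat_grain",
                        obs_years = c(1979, 1985, 1996),
                        rain_mean = 355, rain_shape = 8,
                        model_id = "three", params = NULL,
                        iparams = input_params(), x0_toc = 45,
                        x0_shares = NULL, seed = 1) {
  structure_ <- build_pool_structure(model_id)
  if (is.null(params)) params <- default_parameters(structure_)
  n_years <- length(years)
  if (!is.list(treatments))
    treatments <- rep(list(rep(treatments, length.out = n_years)), n_fields)
  if (length(treatments) != n_fields)
    stop("need one treatment template per field", call. = FALSE)
  treatments <- lapply(treatments, function(tr) {
    if (length(tr) != n_years)
      stop("treatment template length must match trial years", call. = FALSE)
    check_schedule(tr)
  })
  if (!is.list(obs_years)) obs_years <- rep(list(obs_years), n_fields)
  for (oy in obs_years) {
    if (!all(oy %in% years))
      stop("observation year outside trial years", call. = FALSE)
    if (length(oy) < 2)
      stop("at least 2 observations per field required", call. = FALSE)
  }
  if (rain_mean <= 0 || rain_shape <= 0)
    stop("rainfall regime must be positive", call. = FALSE)
  out <- list(n_fields = as.integer(n_fields), years = as.integer(years),
              treatments = treatments, obs_years = obs_years,
              rain_mean = rain_mean, rain_shape = rain_shape,
              model_id = model_id, params = params, iparams = iparams,
              x0_toc = x0_toc,
              x0_shares = x0_shares %||% default_x0_shares(structure_),
              seed = as.integer(seed))
  class(out) <- "site_config"
  out
}

# apply template overrides; shrinking n_fields trims the per-field lists
template_overrides <- function(cfg, over) {
  cfg <- modifyList(cfg, over)
  if (!is.null(over$n_fields) && is.null(over$treatments) &&
      over$n_fields < length(cfg$treatments))
    cfg$treatments <- cfg$treatments[seq_len(over$n_fields)]
  cfg
}

#' Tarlee-style site template
#'
#' Three fields over 1979-1997 under the long-term rotation treatments
#' of the South Australian trial (continuous wheat; wheat-fallow;
#' wheat-pasture; hay cuts in 1988-89 and a closing fallow), sampled in
#' 1979, 1985 and 1996, with a Mediterranean winter-rainfall regime
#' averaging 355 mm.
#'
#' @param ... Overrides passed on to [site_config()].
#' @return A `site_config`.
#' @export
tarlee_template <- function(...) {
  years <- 1979:1997
  f1 <- ifelse(years <= 1987, "wheat_grain",
        ifelse(years <= 1989, "wheat_hay",
        ifelse(years <= 1996, "wheat_grain", "fallow")))
  f2 <- ifelse(years == 1989, "wheat_hay",
        ifelse(years == 1997, "fallow",
        ifelse(years %% 2 == 1, "wheat_grain", "fallow")))
  f3 <- ifelse(years <= 1987, "wheat_pasture",
        ifelse(years <= 1989, "wheat_hay",
        ifelse(years <= 1996, "wheat_pasture", "fallow")))
  cfg <- list(n_fields = 3, years = years,
              treatments = list(f1, f2, f3),
              obs_years = c(1979, 1985, 1996),
              rain_mean = 355, rain_shape = 8)
  do.call(site_config, template_overrides(cfg, list(...)))
}

#' Brigalow-style site template
#'
#' Three soil types cleared of brigalow forest in 1982 and cropped over
#' an 18-year period: fallow in 1983 and 1993, sorghum in 1984, 1995,
#' 1997 and 1999, wheat otherwise, under a semi-arid subtropical
#' rainfall regime.  The sparse observation years (1982, 1987, 1992,
#' 1997) are synthetic stand-ins: the source trial's sampling years are
#' not enumerated here.
#'
#' @param ... Overrides passed on to [site_config()].
#' @return A `site_config`.
#' @export
brigalow_template <- function(...) {
  years <- 1982:1999
  sched <- rep("wheat_grain", length(years))
  sched[years == 1982] <- "cleared"
  sched[years %in% c(1983, 1993)] <- "fallow"
  sched[years %in% c(1984, 1995, 1997, 1999)] <- "sorghum"
  cfg <- list(n_fields = 3, years = years,
              treatments = list(sched, sched, sched),
              obs_years = c(1982, 1987, 1992, 1997),
              rain_mean = 500, rain_shape = 6)
  do.call(site_config, template_overrides(cfg, list(...)))
}

#' Generate a synthetic site
#'
#' Simulates, deterministically for a given seed: shared annual
#' growing-season rainfall (Gamma), per-field dry matter and carbon
#' inputs, latent pool trajectories with process noise, and sparse
#' noisy TOC observations.  Truths are returned for recovery tests;
#' with `obs_sd = 0` observations equal the latent TOC exactly.
#'
#' @param config A [site_config()].
#' @return List of class `soc_synthetic` with `sites` (list of
#'   [soc_site()]), and `truth` (`params`, `iparams`, per-field
#'   `trajectories` and dry-matter series `xw`).
#' @export
#' @examples
#' syn <- make_site(site_config(n_fields = 1, seed = 42))
#' syn$sites[[1]]
make_site <- function(config) {
  stopifnot(inherits(config, "site_config"))
  set.seed(config$seed)
  st <- build_pool_structure(config$model_id)
  pars <- config$params
  ipars <- config$iparams
  n_years <- length(config$years)
  rain <- rgamma(n_years, shape = config$rain_shape,
                 rate = config$rain_shape / config$rain_mean)
  x0 <- setNames(numeric(length(st$pools)), st$pools)
  iom <- if (length(st$constant)) pars$iom_mass else 0
  shares <- config$x0_shares[st$decaying]
  x0[st$decaying] <- max(config$x0_toc - iom, 0) * as.numeric(shares)
  if (length(st$constant)) x0[st$constant] <- pars$iom_mass
  sites <- vector("list", config$n_fields)
  trajs <- xws <- vector("list", config$n_fields)
  for (i in seq_len(config$n_fields)) {
    tr <- config$treatments[[i]]
    xw <- simulate_dry_matter(rain, tr, ipars)
    inputs <- carbon_input(xw, tr, ipars)
    traj <- simulate_process(st, pars, inputs[-n_years], x0, noise = TRUE)
    traj$year <- config$years
    oy <- config$obs_years[[i]]
    idx <- match(oy, config$years)
    obs <- data.frame(year = oy,
                      toc = traj$toc[idx] + rnorm(length(oy), 0,
                                                  pars$obs_sd))
    sites[[i]] <- soc_site(field_id = i, years = config$years,
                           treatments = tr, rain_mm = rain, obs = obs)
    trajs[[i]] <- traj
    xws[[i]] <- xw
  }
  structure(list(sites = sites,
                 truth = list(params = pars, iparams = ipars,
                              trajectories = trajs, xw = xws,
                              rain = rain),
                 config = config),
            class = "soc_synthetic")
}

#' @export
print.soc_synthetic <- function(x, ...) {
  cat("Synthetic SOC site: ", x$config$model_id, "-pool model, ",
      x$config$n_fields, " field(s), years ",
      min(x$config$years), "-", max(x$config$years), "\n", sep = "")
  invisible(x)
}
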