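#' Prior distribution for a single parameter
#'
#' Supported families: `lognormal` (`meanlog`, `sdlog`), `normal`
#' (`mean`, `sd`), `uniform` (`min`, `max`) and `beta` (`shape1`,
#' `shape2`).  Each prior carries an informativeness classification used
#' only for reporting.  The family also fixes the unconstrained
#' parameterisation used by the sampler: log for lognormal, (scaled)
#' logit for beta/uniform, identity for normal.
#'
#' @param family Distribution family name.
#' @param ... Hyperparameters of the family (see above).
#' @param class One of `"informative"`, `"weakly_informative"`,
#'   `"uninformative"`.
#' @return An object of class `soc_prior`.
#' @export
#' @examples
#' prior("lognormal", meanlog = log(0.1), sdlog = 0.5)
#' prior("uniform", min = 0, max = 1, class = "uninformative")
prior <- function(family = c("lognormal", "normal", "uniform", "beta"), ...,
                  class = c("weakly_informative", "informative",
                            "uninformative")) {
  family <- match.arg(family)
  class <- match.arg(class)
  hp <- list(...)
  need <- switch(family,
    lognormal = c("meanlog", "sdlog"), normal = c("mean", "sd"),
    uniform = c("min", "max"), beta = c("shape1", "shape2"))
  if (!all(need %in% names(hp)))
    stop(family, " prior needs hyperparameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (family == "uniform" && hp$max <= hp$min)
    stop("uniform prior needs max > min", call. = FALSE)
  out <- list(family = family, hyper = hp[need], class = class)
  class(out) <- "soc_prior"
  out
}

#' @export
print.soc_prior <- function(x, ...) {
  cat(x$family, "(", paste(sprintf("%s=%g", names(x$hyper),
                                   unlist(x$hyper)), collapse = ", "),
      ") [", x$class, "]\n", sep = "")
  invisible(x)
}

prior_logdens <- function(pr, x) {
  h <- pr$hyper
  switch(pr$family,
    lognormal = dlnorm(x, h$meanlog, h$sdlog, log = TRUE),
    normal    = dnorm(x, h$mean, h$sd, log = TRUE),
    uniform   = dunif(x, h$min, h$max, log = TRUE),
    beta      = dbeta(x, h$shape1, h$shape2, log = TRUE))
}

prior_sample <- function(pr, n = 1) {
  h <- pr$hyper
  switch(pr$family,
    lognormal = rlnorm(n, h$meanlog, h$sdlog),
    normal    = rnorm(n, h$mean, h$sd),
    uniform   = runif(n, h$min, h$max),
    beta      = rbeta(n, h$shape1, h$shape2))
}

# unconstrained <-> natural transforms (prior-driven); log_jac is the log
# absolute Jacobian |d natural / d unconstrained| added to the log target
prior_to_unc <- function(pr, x) {
  h <- pr$hyper
  switch(pr$family,
    lognormal = log(x),
    normal    = x,
    uniform   = qlogis((x - h$min) / (h$max - h$min)),
    beta      = qlogis(x))
}

prior_from_unc <- function(pr, phi) {
  h <- pr$hyper
  switch(pr$family,
    lognormal = exp(phi),
    normal    = phi,
    uniform   = h$min + (h$max - h$min) * plogis(phi),
    beta      = plogis(phi))
}

prior_log_jac <- function(pr, phi) {
  h <- pr$hyper
  switch(pr$family,
    lognormal = phi,
    normal    = 0,
    uniform   = log(h$max - h$min) + plogis(phi, log.p = TRUE) +
                plogis(-phi, log.p = TRUE),
    beta      = plogis(phi, log.p = TRUE) + plogis(-phi, log.p = TRUE))
}

#' Collection of priors
#'
#' A named list of [prior()] objects, one per sampled parameter.  Names
#' refer to entries of [soc_params()] or [input_params()] (e.g. `K_C`
#' for `decay_rates["C"]`, `C_to_BIO` for a transfer fraction,
#' `iom_mass`, `process_sd`, `obs_sd`, `yield_coef`, `input_sd_log`).
#'
#' @param ... Named [prior()] objects.
#' @return An object of class `prior_set`.
#' @export
#' @examples
#' prior_set(K_C = prior("lognormal", meanlog = log(0.1), sdlog = 0.5))
prior_set <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "soc_prior"))
    ps <- ps[[1]]
  if (is.null(names(ps)) || any(names(ps) == ""))
    stop("all priors must be named", call. = FALSE)
  ok <- vapply(ps, inherits, logical(1), "soc_prior")
  if (!all(ok)) stop("all entries must be prior() objects", call. = FALSE)
  class(ps) <- "prior_set"
  ps
}

#' Default priors for a pool structure
#'
#' Weakly informative log-normal priors centred on the literature decay
#' rates of [default_parameters()], a log-normal IOM-mass prior around
#' 4 Mg C/ha, and log-normal noise-scale priors.  These are declared
#' package defaults, not values taken from any specific study.
#'
#' @param structure A [build_pool_structure()] object.
#' @param include Character vector choosing which blocks to include,
#'   subset of `c("decay", "iom", "noise")`.
#' @return A [prior_set()].
#' @export
default_priors <- function(structure,
                           include = c("decay", "iom", "noise")) {
  k_med <- c(C = 0.1, DPM = 10, RPM = 0.3, BIO = 0.66, HUM = 0.02)
  ps <- list()
  if ("decay" %in% include)
    for (pool in structure$decaying)
      ps[[paste0("K_", pool)]] <-
        prior("lognormal", meanlog = log(k_med[[pool]]), sdlog = 0.5)
  if ("iom" %in% include && length(structure$constant))
    ps$iom_mass <- prior("lognormal", meanlog = log(4), sdlog = 0.5)
  if ("noise" %in% include) {
    ps$process_sd <- prior("lognormal", meanlog = log(0.5), sdlog = 0.5)
    ps$obs_sd <- prior("lognormal", meanlog = log(1.5), sdlog = 0.5)
  }
  prior_set(ps)
}

#' Joint log prior density
#'
#' Sum of component log densities of `values` under `priors`.  Every
#' entry of `values` must have a prior; values outside a prior's support
#' give `-Inf`.
#'
#' @param values Named numeric vector of parameter values.
#' @param priors A [prior_set()].
#' @return Scalar log density.
#' @export
#' @examples
#' log_prior(c(u = 0.5), prior_set(u = prior("uniform", min = 0, max = 1)))
log_prior <- function(values, priors) {
  stopifnot(inherits(priors, "prior_set"))
  miss <- setdiff(names(values), names(priors))
  if (length(miss))
    stop("no prior given for: ", paste(miss, collapse = ", "), call. = FALSE)
  sum(vapply(names(values),
             function(nm) prior_logdens(priors[[nm]], values[[nm]]),
             numeric(1)))
}
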