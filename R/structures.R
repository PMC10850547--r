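#' Pool topology of a soil carbon model
#'
#' Builds the fixed pool structure for one of the four SOC model
#' topologies.  The one-pool model treats total SOC as a single
#' homogeneous decaying pool; the two-pool model adds an inert organic
#' matter (IOM) pool that is not subject to biological transformation and
#' stays constant; the three-pool model splits the decomposable carbon
#' into a main pool (C) and a microbial biomass pool (BIO); the five-pool
#' model keeps the full RothC partition into DPM, RPM, BIO, HUM and IOM.
#'
#' Routes list, per decaying source pool, the destination pools of the
#' decayed mass together with the name of the transfer-fraction parameter
#' governing each flow; the CO2 share is the implicit remainder so that
#' route fractions plus the CO2 fraction always sum to one.  Constant
#' pools have no routes in or out.
#'
#' @param model_id One of `"one"`, `"two"`, `"three"`, `"five"`.
#' @return An object of class `pool_structure` with elements `model_id`,
#'   `pools`, `decaying`, `constant`, `routes` and `input_split`.
#' @export
#' @examples
#' build_pool_structure("three")
build_pool_structure <- function(model_id) {
  if (length(model_id) != 1L || !model_id %in% c("one", "two", "three", "five"))
    stop("unknown model_id '", paste(model_id, collapse = ","),
         "'; must be one of: one, two, three, five", call. = FALSE)
  s <- switch(model_id,
    one = list(
      pools = "C", decaying = "C", constant = character(),
      routes = list(C = list()),
      input_split = c(C = "split_C")),
    two = list(
      pools = c("C", "IOM"), decaying = "C", constant = "IOM",
      routes = list(C = list()),
      input_split = c(C = "split_C")),
    three = list(
      pools = c("C", "BIO", "IOM"), decaying = c("C", "BIO"),
      constant = "IOM",
      routes = list(
        C   = list(BIO = "C_to_BIO"),
        BIO = list(BIO = "BIO_to_BIO", C = "BIO_to_C")),
      input_split = c(C = "split_C")),
    five = list(
      pools = c("DPM", "RPM", "BIO", "HUM", "IOM"),
      decaying = c("DPM", "RPM", "BIO", "HUM"), constant = "IOM",
      routes = list(
        DPM = list(BIO = "DPM_to_BIO", HUM = "DPM_to_HUM"),
        RPM = list(BIO = "RPM_to_BIO", HUM = "RPM_to_HUM"),
        BIO = list(BIO = "BIO_to_BIO", HUM = "BIO_to_HUM"),
        HUM = list(BIO = "HUM_to_BIO", HUM = "HUM_to_HUM")),
      input_split = c(DPM = "split_DPM", RPM = "split_RPM")))
  s$model_id <- model_id
  class(s) <- "pool_structure"
  s
}

#' @export
print.pool_structure <- function(x, ...) {
  cat("SOC pool structure: ", x$model_id, "-pool model\n", sep = "")
  cat("  pools:   ", paste(x$pools, collapse = ", "), "\n")
  if (length(x$constant))
    cat("  constant:", paste(x$constant, collapse = ", "), "\n")
  for (src in names(x$routes)) {
    dests <- names(x$routes[[src]])
    cat("  ", src, " -> ",
        paste(c(dests, "CO2"), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Carbon process and observation parameters
#'
#' Assembles and validates the parameter set of a pool structure: annual
#' first-order decay rates (per year), transfer fractions routing decayed
#' carbon between pools (the CO2 share is the remainder), the constant
#' IOM mass (Mg C/ha, models with an IOM pool), and the additive Gaussian
#' process and observation noise standard deviations (Mg C/ha).
#'
#' @param structure A [build_pool_structure()] object.
#' @param decay_rates Named vector of nonnegative decay rates, one per
#'   decaying pool.
#' @param transfer_fractions Named vector in `[0,1]` covering every route
#'   parameter of the structure plus the plant-input split parameters;
#'   per-source route fractions must sum to at most one.
#' @param iom_mass Nonnegative IOM mass (required when the structure has
#'   a constant pool).
#' @param process_sd,obs_sd Nonnegative noise standard deviations.
#' @return An object of class `soc_params`.
#' @seealso [default_parameters()] for literature-based defaults.
#' @export
soc_params <- function(structure, decay_rates, transfer_fractions,
                       iom_mass = 0, process_sd = 0, obs_sd = 0) {
  stopifnot(inherits(structure, "pool_structure"))
  missing_k <- setdiff(structure$decaying, names(decay_rates))
  if (length(missing_k))
    stop("missing decay rates for: ", paste(missing_k, collapse = ", "),
         call. = FALSE)
  if (any(decay_rates[structure$decaying] < 0))
    stop("decay rates must be nonnegative", call. = FALSE)
  needed <- unique(c(unlist(lapply(structure$routes, unlist)),
                     unname(structure$input_split)))
  missing_f <- setdiff(needed, names(transfer_fractions))
  if (length(missing_f))
    stop("missing transfer fractions: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  tf <- transfer_fractions[needed]
  if (any(tf < 0 | tf > 1))
    stop("transfer fractions must lie in [0, 1]", call. = FALSE)
  for (src in names(structure$routes)) {
    pars <- unlist(structure$routes[[src]])
    if (length(pars) && sum(transfer_fractions[pars]) > 1 + 1e-12)
      stop("transfer fractions leaving pool ", src, " exceed 1", call. = FALSE)
  }
  split_pars <- unname(structure$input_split)
  if (abs(sum(transfer_fractions[split_pars]) - 1) > 1e-8)
    stop("plant-input split fractions must sum to 1", call. = FALSE)
  if (length(structure$constant) && (is.na(iom_mass) || iom_mass < 0))
    stop("iom_mass must be nonnegative", call. = FALSE)
  if (process_sd < 0 || obs_sd < 0)
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  out <- list(model_id = structure$model_id,
              decay_rates = decay_rates[structure$decaying],
              transfer_fractions = transfer_fractions,
              iom_mass = if (length(structure$constant)) iom_mass else 0,
              process_sd = process_sd, obs_sd = obs_sd)
  class(out) <- "soc_params"
  out
}

#' Default carbon parameters for a pool structure
#'
#' Literature-based defaults: SOC-scale decay around 0.1/yr, RothC pool
#' rates (DPM 10, RPM 0.3, BIO 0.66, HUM 0.02 per year), plant input
#' split DPM:RPM = 0.59:0.41 (arable convention), and the decayed
#' non-CO2 share split BIO:HUM = 0.46:0.54 (so with a typical CO2 share
#' of 0.625 the route fractions are 0.1725 to BIO and 0.2025 to HUM).
#' All values are overridable.
#'
#' @param structure A [build_pool_structure()] object.
#' @param ... Named overrides for any element of the returned object
#'   (e.g. `iom_mass = 8`, `decay_rates = c(C = 0.05, BIO = 0.5)`).
#' @return A validated [soc_params()] object.
#' @export
#' @examples
#' default_parameters(build_pool_structure("five"))
default_parameters <- function(structure, ...) {
  k_all <- c(C = 0.1, DPM = 10, RPM = 0.3, BIO = 0.66, HUM = 0.02)
  tf <- c(split_C = 1, split_DPM = 0.59, split_RPM = 0.41,
          C_to_BIO = 0.17, BIO_to_BIO = 0.17, BIO_to_C = 0.20,
          DPM_to_BIO = 0.1725, DPM_to_HUM = 0.2025,
          RPM_to_BIO = 0.1725, RPM_to_HUM = 0.2025,
          BIO_to_HUM = 0.2025,
          HUM_to_BIO = 0.1725, HUM_to_HUM = 0.2025)
  args <- list(structure = structure,
               decay_rates = k_all[structure$decaying],
               transfer_fractions = tf,
               iom_mass = 4, process_sd = 0.5, obs_sd = 1.5)
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("decay_rates", "transfer_fractions")) {
      args[[nm]][names(over[[nm]])] <- over[[nm]]
    } else args[[nm]] <- over[[nm]]
  }
  do.call(soc_params, args)
}

#' Annual linear system of the carbon process
#'
#' Discretises the pool flows to an annual time step using the survival
#' fraction `exp(-K)`: a decaying pool retains `exp(-K)` of its mass and
#' the decayed share `1 - exp(-K)` is divided among the destination pools
#' by the transfer fractions, the remainder leaving as CO2.  Constant
#' pools are unit self-loops.  The observation maps state to total
#' organic carbon (all-ones row).
#'
#' @param structure A [build_pool_structure()] object.
#' @param params A matching [soc_params()] object.
#' @return A list of class `soc_linear_system` with transition matrix
#'   `A` (destination x source), input-allocation vector `b`, process
#'   noise covariance `Q` (per-pool sds proportional to nominal pool
#'   shares, normalised so `process_sd` is the TOC-scale sd), the
#'   observation vector `H`, observation variance `R`, per-pool annual
#'   CO2 emission fractions `co2_frac`, and index bookkeeping for
#'   decaying/constant pools.
#' @export
build_linear_system <- function(structure, params) {
  stopifnot(inherits(structure, "pool_structure"),
            inherits(params, "soc_params"))
  pools <- structure$pools
  p <- length(pools)
  A <- matrix(0, p, p, dimnames = list(pools, pools))
  co2 <- setNames(numeric(p), pools)
  tf <- params$transfer_fractions
  for (j in pools) {
    if (j %in% structure$constant) { A[j, j] <- 1; next }
    K <- params$decay_rates[[j]]
    surv <- exp(-K)
    A[j, j] <- surv
    dec <- 1 - surv
    routed <- 0
    for (dest in names(structure$routes[[j]])) {
      frac <- tf[[structure$routes[[j]][[dest]]]]
      A[dest, j] <- A[dest, j] + dec * frac
      routed <- routed + frac
    }
    if (routed > 1 + 1e-12)
      stop("transfer fractions leaving pool ", j, " exceed 1", call. = FALSE)
    co2[j] <- dec * (1 - routed)
  }
  b <- setNames(numeric(p), pools)
  for (dest in names(structure$input_split))
    b[dest] <- tf[[structure$input_split[[dest]]]]
  dec_idx <- match(structure$decaying, pools)
  # process noise allocated over decaying pools in proportion to their
  # nominal share, normalised so the TOC-scale noise sd is process_sd
  shares <- default_x0_shares(structure)[structure$decaying]
  nw <- as.numeric(shares) / sqrt(sum(shares^2))
  qdiag <- numeric(p)
  qdiag[dec_idx] <- (params$process_sd * nw)^2
  out <- list(A = A, b = b, Q = diag(qdiag, p), H = rep(1, p),
              R = params$obs_sd^2, co2_frac = co2,
              noise_weights = setNames(nw, structure$decaying),
              pools = pools, decaying_idx = dec_idx,
              constant_idx = match(structure$constant, pools),
              const_mass = if (length(structure$constant))
                setNames(rep(params$iom_mass, length(structure$constant)),
                         structure$constant) else numeric())
  class(out) <- "soc_linear_system"
  out
}

#' Total organic carbon of a state
#'
#' TOC is the summation of all pool masses.  Accepts a state vector of
#' pool masses or a simulated trajectory data frame (sums the pool
#' columns row-wise).
#'
#' @param state Numeric vector of pool masses, or a data frame produced
#'   by [simulate_process()].
#' @return Nonnegative numeric scalar (or vector for a trajectory).
#' @export
#' @examples
#' toc(c(C = 90.484, BIO = 1.903, IOM = 10))
toc <- function(state) {
  if (is.data.frame(state)) {
    pools <- attr(state, "pools")
    if (is.null(pools))
      pools <- setdiff(names(state), c("year", "toc", "co2_cum", "input", "xw"))
    return(rowSums(state[, pools, drop = FALSE]))
  }
  sum(state)
}

#' Forward simulation of the carbon process
#'
#' Applies the annual linear system repeatedly, starting from the state
#' in trial year 1.  `inputs[t]` is the plant carbon input (Mg C/ha)
#' entering during year `t` and so feeding the transition from year `t`
#' to `t+1`; the returned trajectory covers years `1` to
#' `length(inputs) + 1`.  With `noise = TRUE`, additive Gaussian process
#' noise (sd `process_sd`) is applied to the decaying pools at every
#' transition; any negative excursion is clipped to zero and counted in
#' the `clipped` attribute.
#'
#' @param structure,params Pool structure and parameters.
#' @param inputs Numeric vector of nonnegative annual carbon inputs.
#' @param x0 Initial pool masses (named or in pool order), Mg C/ha.
#' @param noise Add process noise? Default `FALSE`.
#' @param seed Optional integer seed (noise runs are reproducible).
#' @return Data frame with columns `year`, one per pool, `toc`,
#'   `co2_cum` and `input`; attributes `pools` and `clipped`.
#' @export
#' @examples
#' st <- build_pool_structure("three")
#' pp <- default_parameters(st, decay_rates = c(C = 0.1, BIO = 0.66),
#'                          transfer_fractions = c(C_to_BIO = 0.2),
#'                          iom_mass = 10, process_sd = 0, obs_sd = 0)
#' simulate_process(st, pp, inputs = 0, x0 = c(C = 100, BIO = 0, IOM = 10))
simulate_process <- function(structure, params, inputs, x0,
                             noise = FALSE, seed = NULL) {
  sys <- build_linear_system(structure, params)
  T_tr <- length(inputs)
  if (T_tr < 1) stop("need at least one annual input", call. = FALSE)
  if (any(inputs < 0)) stop("negative carbon input rejected", call. = FALSE)
  p <- length(sys$pools)
  if (length(x0) != p) stop("x0 must have one mass per pool", call. = FALSE)
  if (!is.null(names(x0))) x0 <- x0[sys$pools]
  if (any(x0 < 0)) stop("initial masses must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(NA_real_, T_tr + 1, p, dimnames = list(NULL, sys$pools))
  co2 <- numeric(T_tr + 1)
  X[1, ] <- x0
  clipped <- 0L
  for (t in seq_len(T_tr)) {
    emitted <- sum(sys$co2_frac * X[t, ])
    xn <- drop(sys$A %*% X[t, ]) + sys$b * inputs[t]
    if (noise && params$process_sd > 0) {
      xn[sys$decaying_idx] <- xn[sys$decaying_idx] +
        rnorm(length(sys$decaying_idx), 0,
              sqrt(diag(sys$Q)[sys$decaying_idx]))
      neg <- xn < 0
      clipped <- clipped + sum(neg)
      xn[neg] <- 0
    }
    X[t + 1, ] <- xn
    co2[t + 1] <- co2[t] + emitted
  }
  out <- data.frame(year = seq_len(T_tr + 1), X,
                    toc = rowSums(X), co2_cum = co2,
                    input = c(inputs, NA_real_))
  attr(out, "pools") <- sys$pools
  attr(out, "clipped") <- clipped
  out
}
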