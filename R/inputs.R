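#' Plant input sub-model parameters
#'
#' The nonlinear sub-model converts growing-season rainfall and the
#' annual management treatment into plant dry matter and then into the
#' carbon input feeding the pools.  Dry matter in a cropped year is
#' rainfall-proportional with multiplicative log-normal noise
#' (`X_W = yield_coef * rain * exp(eps)`, `eps ~ N(0, input_sd_log^2)`);
#' fallow and cleared years produce none.  The carbon input is
#' `carbon_content * residue_fraction[treatment] * X_W`.
#'
#' An alternative additive-Gaussian noise mode (`noise = "normal"`,
#' `X_W = yield_coef * rain + input_sd_log * z`, sd in Mg/ha) keeps the
#' joint state-space model exactly linear-Gaussian and is used for
#' oracle cross-checks against the Kalman filter; the log-normal mode is
#' the default.
#'
#' @param yield_coef Dry matter per mm of growing-season rain
#'   (Mg/ha/mm); default 0.01 gives ~3.5 Mg/ha at 355 mm.
#' @param residue_fraction Named vector over treatments of the fraction
#'   of dry matter remaining in the field; fallow and cleared must be 0.
#'   Hay removal implies a lower fraction than grain harvest.
#' @param carbon_content Carbon share of dry matter, default 0.45.
#' @param input_sd_log Noise scale: log-scale sd (lognormal mode) or
#'   Mg/ha sd (normal mode).
#' @param noise `"lognormal"` (default) or `"normal"`.
#' @return An object of class `input_params`.
#' @export
input_params <- function(yield_coef = 0.01,
                         residue_fraction = c(wheat_grain = 0.6,
                                              wheat_hay = 0.3,
                                              wheat_pasture = 0.7,
                                              pasture = 0.8,
                                              sorghum = 0.6,
                                              fallow = 0, cleared = 0),
                         carbon_content = 0.45,
                         input_sd_log = 0.3,
                         noise = c("lognormal", "normal")) {
  noise <- match.arg(noise)
  if (yield_coef <= 0) stop("yield_coef must be positive", call. = FALSE)
  rf <- setNames(rep(0, length(soc_treatments())), soc_treatments())
  rf[names(residue_fraction)] <- residue_fraction
  if (any(rf < 0 | rf > 1))
    stop("residue fractions must lie in [0, 1]", call. = FALSE)
  if (any(rf[.bare_treatments] != 0))
    stop("fallow/cleared years must have residue fraction 0", call. = FALSE)
  if (carbon_content < 0 || carbon_content > 1)
    stop("carbon_content must lie in [0, 1]", call. = FALSE)
  if (input_sd_log < 0)
    stop("input_sd_log must be nonnegative", call. = FALSE)
  out <- list(yield_coef = yield_coef, residue_fraction = rf,
              carbon_content = carbon_content,
              input_sd_log = input_sd_log, noise = noise)
  class(out) <- "input_params"
  out
}

check_schedule <- function(treatments) {
  bad <- setdiff(unique(treatments), soc_treatments())
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(treatments)
}

#' Simulate annual plant dry matter
#'
#' @param rain Numeric vector of nonnegative growing-season rainfall, mm.
#' @param treatments Character vector of treatment labels, same length.
#' @param params An [input_params()] object.
#' @param seed Optional integer seed.
#' @return Numeric vector of dry matter, Mg/ha (zero in fallow and
#'   cleared years).
#' @export
#' @examples
#' simulate_dry_matter(355, "wheat_grain", input_params(input_sd_log = 0))
simulate_dry_matter <- function(rain, treatments, params, seed = NULL) {
  stopifnot(inherits(params, "input_params"))
  if (length(rain) != length(treatments))
    stop("rainfall and schedule lengths differ", call. = FALSE)
  if (any(rain < 0)) stop("negative rainfall rejected", call. = FALSE)
  check_schedule(treatments)
  if (!is.null(seed)) set.seed(seed)
  crop <- treatments %in% .crop_treatments
  xw <- numeric(length(rain))
  base <- params$yield_coef * rain[crop]
  n <- sum(crop)
  if (n) {
    z <- rnorm(n)
    xw[crop] <- if (params$noise == "lognormal")
      base * exp(params$input_sd_log * z)
    else base + params$input_sd_log * z
  }
  xw
}

#' Carbon input from dry matter
#'
#' Deterministic conversion: `carbon_content * residue_fraction * X_W`.
#'
#' @param xw Dry matter series, Mg/ha.
#' @param treatments Treatment labels, same length.
#' @param params An [input_params()] object.
#' @return Annual carbon inputs, Mg C/ha.
#' @export
#' @examples
#' carbon_input(3.55, "wheat_grain", input_params())
carbon_input <- function(xw, treatments, params) {
  stopifnot(inherits(params, "input_params"))
  if (length(xw) != length(treatments))
    stop("dry matter and schedule lengths differ", call. = FALSE)
  check_schedule(treatments)
  unname(params$carbon_content * params$residue_fraction[treatments] * xw)
}
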