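#' Time series for one trial field
#'
#' Bundles the forcing and data of a single field: calendar years of the
#' trial, the per-year management treatment, growing-season rainfall, and
#' the sparse total-organic-carbon observations.
#'
#' @param field_id Identifier (string or integer).
#' @param years Consecutive integer calendar years of the trial.
#' @param treatments Treatment label per year (see [soc_treatments()]).
#' @param rain_mm Nonnegative growing-season rainfall per year, mm.
#' @param obs Data frame with columns `year` and `toc` (Mg C/ha);
#'   observation years must lie within the trial and at least one
#'   observation is required.
#' @return An object of class `soc_site`.
#' @export
soc_site <- function(field_id, years, treatments, rain_mm, obs) {
  if (any(diff(years) != 1L))
    stop("trial years must be consecutive", call. = FALSE)
  if (length(treatments) != length(years) || length(rain_mm) != length(years))
    stop("treatments and rainfall must cover every trial year", call. = FALSE)
  check_schedule(treatments)
  if (any(rain_mm < 0)) stop("negative rainfall rejected", call. = FALSE)
  obs <- as.data.frame(obs)
  if (!all(c("year", "toc") %in% names(obs)))
    stop("obs needs columns year and toc", call. = FALSE)
  if (nrow(obs) < 1) stop("at least one observation required", call. = FALSE)
  if (!all(obs$year %in% years))
    stop("observation year outside trial years", call. = FALSE)
  obs <- obs[order(obs$year), , drop = FALSE]
  structure(list(field_id = field_id, years = as.integer(years),
                 treatments = as.character(treatments),
                 rain_mm = as.numeric(rain_mm), obs = obs),
            class = "soc_site")
}

#' @export
print.soc_site <- function(x, ...) {
  cat("SOC site series, field ", x$field_id, ": years ",
      min(x$years), "-", max(x$years), ", ", nrow(x$obs),
      " TOC observations (", paste(x$obs$year, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

as_site_list <- function(sites) {
  if (inherits(sites, "soc_site")) list(sites)
  else {
    stopifnot(all(vapply(sites, inherits, logical(1), "soc_site")))
    sites
  }
}

# restrict a site's observations to years <= cutoff (LFO-CV folds)
truncate_obs <- function(site, cutoff_year) {
  site$obs <- site$obs[site$obs$year <= cutoff_year, , drop = FALSE]
  site
}

# years (calendar) carrying at least one observation in any field
obs_events <- function(sites) {
  sites <- as_site_list(sites)
  sort(unique(unlist(lapply(sites, function(s) s$obs$year))))
}
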