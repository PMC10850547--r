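#' Write a site's data files
#'
#' Writes the three flat CSVs consumed by the pipeline: observations
#' (`field,year,toc`), schedule (`field,year,treatment`) and climate
#' (`year,rain_mm`), plus optionally a truth JSON for synthetic sites.
#'
#' @param sites A [soc_site()] or list of fields, or a `soc_synthetic`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"site"`.
#' @return Invisibly, the named vector of paths written.
#' @export
write_site_csv <- function(sites, dir, prefix = "site") {
  synthetic <- inherits(sites, "soc_synthetic")
  if (synthetic) { syn <- sites; sites <- syn$sites }
  sites <- as_site_list(sites)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- do.call(rbind, lapply(sites, function(s)
    data.frame(field = s$field_id, s$obs)))
  sched <- do.call(rbind, lapply(sites, function(s)
    data.frame(field = s$field_id, year = s$years,
               treatment = s$treatments)))
  clim <- data.frame(year = sites[[1]]$years,
                     rain_mm = sites[[1]]$rain_mm)
  paths <- c(observations = file.path(dir, paste0(prefix, "_observations.csv")),
             schedule = file.path(dir, paste0(prefix, "_schedule.csv")),
             climate = file.path(dir, paste0(prefix, "_climate.csv")))
  write.csv(obs, paths["observations"], row.names = FALSE)
  write.csv(sched, paths["schedule"], row.names = FALSE)
  write.csv(clim, paths["climate"], row.names = FALSE)
  if (synthetic) {
    tp <- file.path(dir, paste0(prefix, "_truth.json"))
    tr <- syn$truth
    jsonlite::write_json(list(model_id = syn$config$model_id,
                              params = unclass(tr$params),
                              iparams = unclass(tr$iparams),
                              seed = syn$config$seed),
                         tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

#' Read site data files
#'
#' Counterpart of [write_site_csv()]: assembles one [soc_site()] per
#' field from the observations, schedule and climate CSVs.
#'
#' @param observations,schedule,climate Paths to the three CSVs.
#' @return List of [soc_site()] objects.
#' @export
read_site_csv <- function(observations, schedule, climate) {
  for (pth in c(observations, schedule, climate))
    if (!file.exists(pth))
      stop("input file not found: ", pth, call. = FALSE)
  obs <- read.csv(observations)
  sched <- read.csv(schedule)
  clim <- read.csv(climate)
  fields <- unique(sched$field)
  lapply(fields, function(f) {
    sf <- sched[sched$field == f, ]
    sf <- sf[order(sf$year), ]
    of <- obs[obs$field == f, c("year", "toc")]
    rain <- clim$rain_mm[match(sf$year, clim$year)]
    soc_site(field_id = f, years = sf$year, treatments = sf$treatment,
             rain_mm = rain, obs = of)
  })
}

#' Write a trace as a long CSV
#'
#' Columns `chain,iteration,parameter,value` (iteration indexes retained
#' draws).
#'
#' @param trace A [cpm_mcmc()] trace.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_trace_csv <- function(trace, path) {
  rows <- do.call(rbind, lapply(seq_along(trace$chains), function(ch) {
    d <- trace$chains[[ch]]$draws
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(d)), ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a site template
#'
#' Round-trips a [site_config()] through JSON (parameter objects are
#' rebuilt on read).
#'
#' @param config A `site_config`.
#' @param path JSON file path.
#' @return `write_site_config()` returns the path invisibly;
#'   `read_site_config()` the restored `site_config`.
#' @export
write_site_config <- function(config, path) {
  stopifnot(inherits(config, "site_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$iparams <- unclass(x$iparams)
  # named atomic vectors must become objects, not bare arrays
  x$params$decay_rates <- as.list(x$params$decay_rates)
  x$params$transfer_fractions <- as.list(x$params$transfer_fractions)
  x$iparams$residue_fraction <- as.list(x$iparams$residue_fraction)
  x$x0_shares <- as.list(x$x0_shares)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_site_config
#' @export
read_site_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- build_pool_structure(x$model_id)
  pars <- soc_params(st, decay_rates = unlist(x$params$decay_rates),
                     transfer_fractions = unlist(x$params$transfer_fractions),
                     iom_mass = x$params$iom_mass,
                     process_sd = x$params$process_sd,
                     obs_sd = x$params$obs_sd)
  ip <- x$iparams
  ipars <- input_params(yield_coef = ip$yield_coef,
                        residue_fraction = unlist(ip$residue_fraction),
                        carbon_content = ip$carbon_content,
                        input_sd_log = ip$input_sd_log, noise = ip$noise)
  relist_rows <- function(v) {
    if (is.matrix(v)) lapply(seq_len(nrow(v)), function(i) v[i, ])
    else if (is.list(v)) lapply(v, unlist)
    else v
  }
  site_config(n_fields = x$n_fields, years = x$years,
              treatments = relist_rows(x$treatments),
              obs_years = relist_rows(x$obs_years),
              rain_mean = x$rain_mean, rain_shape = x$rain_shape,
              model_id = x$model_id, params = pars, iparams = ipars,
              x0_toc = x$x0_toc, x0_shares = unlist(x$x0_shares),
              seed = x$seed)
}
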