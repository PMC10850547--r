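#' Simulate a synthetic site to disk
#'
#' Generates a synthetic site from a named template (or a config JSON)
#' and writes the observation/schedule/climate CSVs plus the truth
#' JSON.
#'
#' @param template `"tarlee"`, `"brigalow"`, or the path of a
#'   [write_site_config()] JSON.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param ... Template overrides (ignored when reading a config file).
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(template = "tarlee", out_dir, seed = 1, ...) {
  cfg <- if (file.exists(template)) read_site_config(template)
  else switch(template,
              tarlee = tarlee_template(seed = seed, ...),
              brigalow = brigalow_template(seed = seed, ...),
              stop("unknown template: ", template, call. = FALSE))
  syn <- make_site(cfg)
  paths <- write_site_csv(syn, out_dir, prefix = template)
  invisible(paths)
}

check_run_config <- function(config) {
  needed <- c("observations", "schedule", "climate")
  for (nm in needed) {
    if (is.null(config[[nm]]))
      stop("config misses data path '", nm, "'", call. = FALSE)
    if (!file.exists(config[[nm]]))
      stop("input file not found: ", config[[nm]], call. = FALSE)
  }
  invisible(config)
}

mcmc_config_from <- function(config) {
  mc <- config$mcmc %||% list()
  do.call(soc_mcmc_config, mc)
}

#' Fit a SOC model to site data
#'
#' Reads the three data CSVs, runs [cpm_mcmc()] and writes the artifact
#' bundle: long-format trace CSV, convergence diagnostics CSV, per-field
#' SOC-change summary CSVs, and a JSON manifest capturing the full
#' configuration and seeds for exact replay.  Fails (with no partial
#' outputs) on an invalid configuration.
#'
#' @param config Named list (or path to a JSON file) with elements
#'   `model_id`; data paths `observations`, `schedule`, `climate`;
#'   optional `mcmc` sub-list passed to [soc_mcmc_config()]; optional
#'   `out_dir` (default `"soc_fit"`).
#' @return Invisibly, a list with the trace and the written paths.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  check_run_config(config)
  model_id <- config$model_id %||% "three"
  st <- build_pool_structure(model_id)
  sites <- read_site_csv(config$observations, config$schedule,
                         config$climate)
  cfg <- mcmc_config_from(config)
  priors <- default_priors(st, include = config$prior_blocks %||%
                             c("decay", "iom"))
  out_dir <- config$out_dir %||% "soc_fit"
  trace <- cpm_mcmc(st, sites, priors, cfg,
                    verbose = isTRUE(config$verbose))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trace = file.path(out_dir, "trace.csv"),
             diagnostics = file.path(out_dir, "diagnostics.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_trace_csv(trace, paths[["trace"]])
  diag <- if (cfg$n_chains >= 2) gelman_rubin(trace) else
    data.frame(parameter = trace$param_names, rhat = NA_real_,
               converged = NA)
  write.csv(diag, paths[["diagnostics"]], row.names = FALSE)
  for (i in seq_along(sites)) {
    tm <- toc_draws(trace, field = i)
    sc <- cbind(soc_change(tm)[, c("year", "mean_change", "var_change")],
                credible_band(tm)[, -1])
    pth <- file.path(out_dir, sprintf("soc_change_field_%s.csv",
                                      sites[[i]]$field_id))
    write.csv(sc, pth, row.names = FALSE)
    paths <- c(paths, setNames(pth, paste0("soc_change_", i)))
  }
  jsonlite::write_json(list(command = "fit", model_id = model_id,
                            data = config[c("observations", "schedule",
                                            "climate")],
                            mcmc = cfg,
                            package_version =
                              as.character(utils::packageVersion("socbayes"))),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(list(trace = trace, paths = paths))
}

#' Compare candidate SOC models by LFO-CV
#'
#' Runs [lfo_cv()] for each candidate topology on shared folds and
#' writes the per-fold report CSV plus a ranking JSON.
#'
#' @param config Named list (or JSON path) as in [run_fit()], plus
#'   `candidates` (>= 2 distinct model ids) and optional `L` (default
#'   `max(2, events - 3)`).
#' @return Invisibly, a list with the `elpd_result`s, the ranking data
#'   frame and the written paths.
#' @export
run_select <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  check_run_config(config)
  cands <- unlist(config$candidates)
  if (length(cands) < 2)
    stop("model selection needs at least 2 candidate models",
         call. = FALSE)
  if (anyDuplicated(cands))
    stop("duplicate candidate model ids", call. = FALSE)
  sites <- read_site_csv(config$observations, config$schedule,
                         config$climate)
  events <- obs_events(sites)
  L <- config$L %||% max(2L, length(events) - 3L)
  cfg <- mcmc_config_from(config)
  out_dir <- config$out_dir %||% "soc_select"
  results <- lapply(cands, function(mid) {
    st <- build_pool_structure(mid)
    lfo_cv(st, sites, default_priors(st, include = config$prior_blocks %||%
                                       c("decay", "iom")),
           L = L, config = cfg, verbose = isTRUE(config$verbose))
  })
  ranking <- rank_models(results)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- do.call(rbind, lapply(results, function(r)
    data.frame(model = r$model_id, fold_year = r$folds$year,
               log_pred_density = r$folds$log_pred)))
  paths <- c(report = file.path(out_dir, "elpd_report.csv"),
             ranking = file.path(out_dir, "ranking.json"))
  write.csv(report, paths[["report"]], row.names = FALSE)
  jsonlite::write_json(list(L = L, ranking = ranking, mcmc = cfg),
                       paths[["ranking"]], auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, ranking = ranking, paths = paths))
}

#' Convergence diagnostics for a written trace
#'
#' Reads a long-format trace CSV (as written by [run_fit()]) and
#' reports the Gelman-Rubin statistic per parameter.
#'
#' @param trace_csv Path to the trace CSV.
#' @param out Optional output CSV path.
#' @return The diagnostics data frame.
#' @export
run_diagnose <- function(trace_csv, out = NULL) {
  if (!file.exists(trace_csv))
    stop("input file not found: ", trace_csv, call. = FALSE)
  tr <- read.csv(trace_csv)
  chains <- lapply(split(tr, tr$chain), function(d) {
    m <- do.call(cbind, lapply(split(d$value, d$parameter), identity))
    m
  })
  diag <- gelman_rubin(chains)
  if (!is.null(out)) write.csv(diag, out, row.names = FALSE)
  diag
}
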