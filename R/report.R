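#' Declarative configuration for a full pipeline run
#'
#' A single configuration drives [run_all()]; every element has a default
#' so `hia_config()` alone reproduces the standard synthetic study. Input
#' CSV paths may be supplied instead of the synthetic generator; a
#' configuration can also be loaded from a YAML file with
#' [read_hia_config()].
#'
#' @param synthetic a [synth_config()], used when no input paths are
#'   given.
#' @param readings_csv,demographics_csv,adjacency_csv optional input file
#'   paths (all three required together).
#' @param smoke_threshold smoke-day threshold, ug/m3.
#' @param correct_neph apply nephelometer recalibration?
#' @param calibration a [neph_calibration()].
#' @param response_functions list of [response_function()]s.
#' @param reductions scenario reduction fractions.
#' @param scenario_target scenario target population.
#' @param mc an [mc_spec()], or NULL to skip the Monte Carlo stage.
#' @param beta_form CRF conversion form.
#' @return Object of class `hia_config`.
#' @export
hia_config <- function(synthetic = synth_config(),
                       readings_csv = NULL, demographics_csv = NULL,
                       adjacency_csv = NULL,
                       smoke_threshold = 20.4,
                       correct_neph = FALSE,
                       calibration = neph_calibration(),
                       response_functions = default_response_functions(),
                       reductions = c(0.10, 0.40, 0.70, 0.80, 1.00),
                       scenario_target = "total_population",
                       mc = mc_spec(),
                       beta_form = "log") {
  paths <- c(readings_csv, demographics_csv, adjacency_csv)
  if (length(paths) > 0 && length(paths) != 3)
    stop("readings_csv, demographics_csv and adjacency_csv must be ",
         "supplied together", call. = FALSE)
  structure(list(synthetic = synthetic, readings_csv = readings_csv,
                 demographics_csv = demographics_csv,
                 adjacency_csv = adjacency_csv,
                 smoke_threshold = smoke_threshold,
                 correct_neph = correct_neph, calibration = calibration,
                 response_functions = response_functions,
                 reductions = reductions,
                 scenario_target = scenario_target, mc = mc,
                 beta_form = beta_form),
            class = "hia_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [hia_config()] arguments, with
#' `synthetic` holding [synth_config()] fields and `mc` holding
#' [mc_spec()] fields. Unknown keys are an error, so typos do not
#' silently fall back to defaults.
#'
#' @param path YAML file.
#' @return Object of class `hia_config`.
#' @export
read_hia_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("synthetic", "readings_csv", "demographics_csv",
             "adjacency_csv", "smoke_threshold", "correct_neph",
             "reductions", "scenario_target", "mc", "beta_form")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- y
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    for (nm in c("episode_start", "baseline_start"))
      if (!is.null(s[[nm]])) s[[nm]] <- as.Date(s[[nm]])
    args$synthetic <- do.call(synth_config, s)
  }
  if (!is.null(y$mc)) args$mc <- do.call(mc_spec, y$mc)
  do.call(hia_config, args)
}

read_readings_csv <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  r$date <- as.Date(r$date)
  r
}

#' Rank counties by per-capita burden
#'
#' Sorts county rows in descending order of deaths per 100,000 persons;
#' ties break by county id (ascending), so the ordering is total and
#' stable. Statewide total rows are dropped.
#'
#' @param burdens a `burden_estimate` data.frame (possibly several bound
#'   together).
#' @return The county rows, reordered.
#' @export
rank_per_capita <- function(burdens) {
  b <- burdens[burdens$scope == "county", , drop = FALSE]
  if (nrow(b) == 0) return(b)
  b <- b[order(-b$per_100k, b$county_id), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Run the complete assessment and write all outputs
#'
#' Sequences the whole pipeline under one configuration: input generation
#' (or CSV loading), exposure construction, acute burden under both
#' attribution conventions, chronic annualized burden, the
#' intervention-scenario table, the Monte Carlo exposure-uncertainty
#' interval, a per-capita county ranking, and a machine-readable
#' provenance record (configuration hash, seeds, package and R versions).
#' Outputs are deterministic for a fixed configuration.
#'
#' @param cfg an [hia_config()].
#' @param out_dir output directory (created if needed); NULL writes
#'   nothing and only returns the results.
#' @return Invisibly, a list with `exposure_summary`, `deltas`, `acute`,
#'   `chronic`, `scenarios`, `mc` (list per acute response function, NULL
#'   if disabled), `ranking`, `provenance` and the written `files`.
#' @examples
#' res <- run_all(hia_config(synthetic = synth_config(n_counties = 6)),
#'                out_dir = NULL)
#' res$acute[res$acute$scope == "statewide", ]
#' @export
run_all <- function(cfg = hia_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "hia_config"))
  stage <- "input"
  res <- tryCatch({
    if (is.null(cfg$readings_csv)) {
      study <- generate_study(cfg$synthetic)
      readings <- study$readings
      demo <- study$counties
      adjacency <- study$adjacency
    } else {
      readings <- read_readings_csv(cfg$readings_csv)
      demo <- utils::read.csv(cfg$demographics_csv,
                              stringsAsFactors = FALSE)
      adjacency <- utils::read.csv(cfg$adjacency_csv,
                                   stringsAsFactors = FALSE)
    }

    stage <- "exposure"
    deltas <- build_exposure(readings, adjacency,
                             county_ids = demo$county_id,
                             correct_neph = cfg$correct_neph,
                             calibration = cfg$calibration,
                             smoke_threshold = cfg$smoke_threshold)
    exposure_summary <- summarize_exposure(deltas)

    stage <- "attribution"
    acute_rfs <- Filter(function(r) r$kind != "annual_crf_percent_per_10",
                        cfg$response_functions)
    chronic_rfs <- Filter(function(r) r$kind == "annual_crf_percent_per_10",
                          cfg$response_functions)
    acute <- do.call(rbind, lapply(acute_rfs, run_acute, deltas = deltas,
                                   demo = demo, beta_form = cfg$beta_form))
    chronic <- if (length(chronic_rfs))
      do.call(rbind, lapply(chronic_rfs, run_chronic, deltas = deltas,
                            demo = demo, beta_form = cfg$beta_form))

    stage <- "scenarios"
    scen <- scenario_table(deltas, demo, acute_rfs, cfg$reductions,
                           cfg$scenario_target, cfg$beta_form)

    stage <- "monte-carlo"
    mc <- NULL
    if (!is.null(cfg$mc)) {
      rsd <- if (cfg$mc$rsd_source == "estimated")
        estimate_rsd(readings[readings$period == "episode", ])
      mc <- lapply(acute_rfs, function(rf)
        mc_hia(draw_exposures(deltas, rsd, cfg$mc), demo, rf,
               cfg$beta_form))
    }

    list(exposure_summary = exposure_summary, deltas = deltas,
         acute = acute, chronic = chronic, scenarios = scen, mc = mc,
         ranking = rank_per_capita(acute))
  }, error = function(e)
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))

  res$provenance <- provenance_record(cfg)
  res$files <- if (!is.null(out_dir)) write_outputs(res, out_dir)
  invisible(res)
}

# config hash + versions; enough to regenerate every output byte-for-byte
provenance_record <- function(cfg) {
  canon <- tempfile(fileext = ".yml")
  on.exit(unlink(canon))
  yaml::write_yaml(unclass_recursive(cfg), canon)
  list(config = unclass_recursive(cfg),
       config_md5 = unname(tools::md5sum(canon)),
       seeds = list(synthetic = cfg$synthetic$seed,
                    mc = if (!is.null(cfg$mc)) cfg$mc$seed),
       package_version =
         as.character(utils::packageVersion("smokehia")),
       r_version = R.version.string)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive)
  else if (inherits(x, "Date")) format(x)
  else x
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  files <- c(
    wcsv(cbind(res$exposure_summary, units = "ug/m3"),
         "exposure_summary.csv"),
    wcsv(cbind(as.data.frame(res$deltas), units = "ug/m3"),
         "county_day_deltas.csv"),
    wcsv(cbind(res$acute, units = "deaths"), "burden_acute.csv"),
    wcsv(cbind(res$scenarios, units = "deaths"), "scenario_table.csv"),
    wcsv(cbind(res$ranking, units = "deaths per 100,000"),
         "ranking_per_100k.csv"))
  if (!is.null(res$chronic))
    files <- c(files, wcsv(cbind(res$chronic, units = "deaths/year"),
                           "burden_chronic.csv"))
  if (!is.null(res$mc)) {
    mcdf <- do.call(rbind, lapply(res$mc, function(m)
      data.frame(endpoint = m$endpoint, approach = m$approach,
                 central = m$central, low = m$low, high = m$high,
                 n_draws = m$n_draws, units = "deaths")))
    files <- c(files, wcsv(mcdf, "mc_interval.csv"))
  }
  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(res$provenance, prov, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(files, prov)
}
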