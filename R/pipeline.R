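#' Run the full fatal-burden pipeline
#'
#' Orchestrates validate -> combination rules -> cause mapping -> four-step
#' redistribution -> burden metrics -> output files. Writes, under
#' `out_dir`: `counts.csv` (cause counts with uncertainty),
#' `step_shares.csv`, `idd_share.csv`, `burden.csv` (counts, crude rates
#' and age-standardized rates for deaths and SEYLL; only when a population
#' table is supplied), `exclusions.csv`, and `manifest.json` (config
#' snapshot, input checksums, seeds, version, timings) for reproducibility.
#'
#' @param deaths Path to the deaths CSV, or a [cod_data] object.
#' @param mcod_path Optional path to the long MCOD companion file (ignored
#'   when `deaths` is a [cod_data]).
#' @param map A [cause_map], a directory for [load_cause_map()], or
#'   `"demo"` for the bundled demo map.
#' @param life_table A life table data.frame, a CSV path, or
#'   `"synthetic"` for the bundled synthetic table. Completed with
#'   [complete_life_table()] before use.
#' @param standard A standard population, CSV path, or `"esp2013"`.
#' @param population Optional population table (data.frame or CSV path);
#'   rates are skipped when absent.
#' @param config A [redistribution_config()].
#' @param level Reporting hierarchy level (default 3).
#' @param by Stratifiers for the summaries (default `"year"`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (`summary`,
#'   `burden`, `ensemble`, `manifest`).
#' @export
run_pipeline <- function(deaths, mcod_path = NULL, map = "demo",
                         life_table = "synthetic", standard = "esp2013",
                         population = NULL,
                         config = redistribution_config(),
                         level = 3L, by = "year", out_dir) {
  t0 <- Sys.time()
  checksums <- list()
  if (is.character(deaths)) {
    checksums[basename(deaths)] <- unname(tools::md5sum(deaths))
    if (!is.null(mcod_path))
      checksums[basename(mcod_path)] <- unname(tools::md5sum(mcod_path))
    deaths <- read_death_records(deaths, mcod_path = mcod_path)
  }
  stopifnot(inherits(deaths, "cod_data"))
  if (identical(map, "demo")) map <- demo_cause_map()
  else if (is.character(map)) map <- load_cause_map(map)
  if (identical(life_table, "synthetic")) life_table <- synthetic_life_table()
  else if (is.character(life_table))
    life_table <- complete_life_table(read_life_table(life_table))
  else life_table <- complete_life_table(life_table)
  if (identical(standard, "esp2013")) standard <- esp2013()
  else if (is.character(standard))
    standard <- read_standard_population(standard)
  if (is.character(population)) population <- read_population(population)

  val <- validate_records(deaths)
  kept <- apply_combination_rules(val$kept, map)
  ensemble <- run_redistribution(kept, map, config)
  summary <- summarize_ensemble(ensemble, kept, map, level = level, by = by)
  burden <- NULL
  if (!is.null(population))
    burden <- burden_table(ensemble, kept, life_table, population,
                           standard = standard, map = map, level = level,
                           by = by)

  tables <- list(counts = summary$counts,
                 step_shares = summary$step_shares,
                 idd_share = summary$idd_share,
                 exclusions = data.table::data.table(
                   reason = names(val$exclusions),
                   n = as.integer(val$exclusions)))
  if (!is.null(burden)) tables$burden <- burden
  write_estimates(tables, out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gcredist")),
    r_version = R.version.string,
    config = unclass(config),
    seeds = ensemble$seeds,
    report_years = ensemble$report_years,
    level = level, by = by,
    input_checksums = checksums,
    n_deaths = nrow(kept$deaths),
    exclusions = as.list(val$exclusions),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    dput(manifest, file.path(out_dir, "manifest.json"))
  }
  invisible(list(summary = summary, burden = burden, ensemble = ensemble,
                 manifest = manifest))
}
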