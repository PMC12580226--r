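#' Run manifest
#'
#' Provenance stamp attached to every report: a hash of the effective
#' configuration (parameters, strategies, seeds, cohort size), the
#' count of loaded versus synthetic parameter blocks, and the package
#' version. Identical manifests (ignoring the timestamp) imply
#' bit-identical outputs.
#'
#' @param params A `crc_parameters` object.
#' @param config List of run settings entering the hash.
#' @return A `crc_manifest` list.
#' @export
run_manifest <- function(params, config = list()) {
  prov <- table(factor(params$meta, levels = c("loaded", "synthetic")))
  structure(list(
    config_hash = rlang::hash(list(meta = params$meta, config = config,
                                   params = unclass(params))),
    provenance = c(loaded = unname(prov[["loaded"]]),
                   synthetic = unname(prov[["synthetic"]])),
    synthetic_parameters = any(params$meta == "synthetic"),
    seed = config$seed %||% NA_integer_,
    n_individuals = config$n_individuals %||% NA_integer_,
    package_version = as.character(utils::packageVersion("crcscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "crc_manifest")
}

synthetic_banner <- function(manifest) {
  if (manifest$synthetic_parameters) {
    "SYNTHETIC PARAMETERS - results not comparable to published analyses"
  } else {
    NULL
  }
}

#' Run one strategy-versus-comparator scenario
#'
#' Simulates the strategy and its comparator on the same cohort with
#' common random numbers, compares them, and (optionally) writes the
#' outcome table, the comparison, and a manifest to `out_dir`. Reports
#' computed from any synthetic parameter block carry a visible banner.
#'
#' @param params A `crc_parameters` object.
#' @param strategy A [strategy_spec()].
#' @param comparator Comparator [strategy_spec()] or `NULL` for no
#'   screening.
#' @param n_individuals Cohort size (default from the parameter set's
#'   population block).
#' @param seed Simulation seed.
#' @param dukesd_x10 If `TRUE`, apply [apply_dukes_d_scenario()] first.
#' @param out_dir Optional output directory for CSV/JSON files.
#' @return List with `outcomes` (strategy and comparator), `comparison`,
#'   and `manifest`.
#' @export
run_scenario <- function(params, strategy, comparator = NULL,
                         n_individuals = NULL, seed = 1L,
                         dukesd_x10 = FALSE, out_dir = NULL) {
  validate_parameters(params)
  if (isTRUE(dukesd_x10)) params <- apply_dukes_d_scenario(params)
  n <- as.integer(n_individuals %||% params$population$n_individuals)
  spec <- population_spec(n, params$population$age_weights,
                          params$population$sex_weights, seed = seed)
  pop <- sample_population(spec)
  out_i <- run_cohort(pop, params, strategy, seed = seed)
  out_c <- run_cohort(pop, params, comparator, seed = seed)
  cmp <- compare_strategies(out_i, out_c, params$econ)
  manifest <- run_manifest(params, list(seed = seed, n_individuals = n,
                                        strategy = unclass(strategy),
                                        comparator = if (!is.null(comparator)) unclass(comparator),
                                        dukesd_x10 = dukesd_x10))
  result <- list(outcomes = list(strategy = out_i, comparator = out_c),
                 comparison = cmp, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- outcome_table(list(strategy = out_i, comparator = out_c), cmp, manifest)
    write_report_csv(tab, file.path(out_dir, "scenario.csv"), manifest)
    jsonlite::write_json(manifest_json(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

# rows follow the conventional cost-effectiveness table layout
outcome_table <- function(outcomes, comparison = NULL, manifest = NULL) {
  cols <- lapply(outcomes, function(o) {
    c("Cost (per person)" = round(o$mean_discounted_cost),
      "CRC cases (per 10^5 persons)" = round(o$crc_cases_per_1e5),
      "CRC death (per 10^5 persons)" = round(o$crc_deaths_per_1e5),
      "QALYs (per person)" = round(o$mean_discounted_qalys, 4))
  })
  tab <- data.frame(row = names(cols[[1]]), check.names = FALSE)
  for (nm in names(cols)) tab[[nm]] <- unname(cols[[nm]])
  if (!is.null(comparison)) {
    icer_lab <- switch(comparison$verdict,
                       Dominant = "Dominant", Dominated = "Dominated",
                       Equivalent = "Equivalent",
                       EqualEffectCostDiffers = "Equal effect, cost differs",
                       ICER = format(round(comparison$icer), big.mark = ","))
    icer_row <- stats::setNames(as.list(rep(NA, ncol(tab))), names(tab))
    icer_row$row <- "ICER (per QALY)"
    icer_row[[names(cols)[1]]] <- icer_lab
    tab <- rbind(tab, as.data.frame(icer_row, check.names = FALSE))
  }
  tab
}

write_report_csv <- function(tab, path, manifest) {
  con <- file(path, "w")
  on.exit(close(con))
  banner <- synthetic_banner(manifest)
  if (!is.null(banner)) writeLines(paste0("# ", banner), con)
  writeLines(paste0("# manifest: ", manifest$config_hash), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

manifest_json <- function(m) {
  m$provenance <- as.list(m$provenance)
  unclass(m)
}

#' Load a scenario grid definition
#'
#' Reads a YAML scenarios file describing one or more grids, each a
#' list of uptake scenarios plus a reference comparator (either an
#' explicit strategy or `reference_mode: same_uptake_fit`, which
#' compares each TCS scenario against FIT-based screening at the same
#' uptake with 70% follow-up). The bundled file
#' `system.file("extdata", "scenarios.yaml", package = "crcscreen")`
#' enumerates the standard 8 + 6 + 4 scenario grid (FIT-based,
#' TCS-based, combined).
#'
#' @param path Path to a scenarios YAML file (default: bundled grid).
#' @return Named list of grid definitions.
#' @export
load_scenarios <- function(path = system.file("extdata", "scenarios.yaml",
                                              package = "crcscreen")) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$grids)) stop("scenarios file must have a top-level 'grids' block", call. = FALSE)
  raw$grids
}

strategy_from_config <- function(cfg) {
  args <- cfg[setdiff(names(cfg), c("label", "reference_mode"))]
  do.call(strategy_spec, args)
}

#' Run a full scenario grid
#'
#' Evaluates every scenario of every grid in a scenarios file on a
#' common cohort (common random numbers throughout), producing one
#' table per grid with the conventional row labels and one column per
#' uptake scenario, plus the ICER-versus-reference row. Writes CSVs and
#' a manifest when `out_dir` is given; rerunning with the same settings
#' reproduces the CSV bytes exactly.
#'
#' @param params A `crc_parameters` object.
#' @param scenarios Grid definitions from [load_scenarios()] (default:
#'   the bundled grid).
#' @param n_individuals Cohort size per scenario.
#' @param seed Simulation seed (shared: common random numbers).
#' @param dukesd_x10 Apply the Dukes-D cost scenario first.
#' @param out_dir Optional output directory.
#' @return Named list of data frames (one per grid), with the manifest
#'   as attribute `"manifest"`.
#' @export
run_grid <- function(params, scenarios = load_scenarios(),
                     n_individuals = NULL, seed = 1L,
                     dukesd_x10 = FALSE, out_dir = NULL) {
  validate_parameters(params)
  if (isTRUE(dukesd_x10)) params <- apply_dukes_d_scenario(params)
  n <- as.integer(n_individuals %||% params$population$n_individuals)
  spec <- population_spec(n, params$population$age_weights,
                          params$population$sex_weights, seed = seed)
  pop <- sample_population(spec)

  manifest <- run_manifest(params, list(seed = seed, n_individuals = n,
                                        scenarios = scenarios,
                                        dukesd_x10 = dukesd_x10))
  cache <- new.env(parent = emptyenv())
  eval_strategy <- function(st) {
    key <- rlang::hash(unclass(st))
    if (is.null(cache[[key]])) cache[[key]] <- run_cohort(pop, params, st, seed = seed)
    cache[[key]]
  }

  grids <- list()
  for (grid_name in names(scenarios)) {
    g <- scenarios[[grid_name]]
    ref_mode <- g$reference_mode %||% "explicit"
    ref_out <- if (ref_mode == "explicit") {
      if (is.null(g$reference)) stop("grid '", grid_name, "': no reference strategy", call. = FALSE)
      eval_strategy(strategy_from_config(g$reference))
    } else NULL

    labels <- vapply(g$scenarios, function(sc) sc$label %||% "scenario", character(1))
    rows <- c("Cost (per person)", "CRC cases (per 10^5 persons)",
              "CRC death (per 10^5 persons)", "QALYs (per person)",
              "ICER (per QALY)")
    tab <- data.frame(row = rows, check.names = FALSE)
    raw <- data.frame(row = c("cost", "cases_per_1e5", "deaths_per_1e5",
                              "qalys", "icer"), check.names = FALSE)
    for (k in seq_along(g$scenarios)) {
      sc <- g$scenarios[[k]]
      st <- strategy_from_config(sc)
      out <- eval_strategy(st)
      ref_k <- if (ref_mode == "same_uptake_fit") {
        eval_strategy(strategy_spec("FIT_based",
                                    fit_uptake = st$primary_tcs_uptake,
                                    tcs_after_fit_uptake = 0.70))
      } else ref_out
      cmp <- compare_strategies(out, ref_k, params$econ)
      icer_lab <- switch(cmp$verdict,
                         Dominant = "Dominant", Dominated = "Dominated",
                         Equivalent = "Equivalent",
                         EqualEffectCostDiffers = "Equal effect, cost differs",
                         ICER = format(round(cmp$icer), big.mark = ","))
      tab[[labels[k]]] <- c(format(round(out$mean_discounted_cost), big.mark = ","),
                            format(round(out$crc_cases_per_1e5), big.mark = ","),
                            format(round(out$crc_deaths_per_1e5), big.mark = ","),
                            sprintf("%.4f", out$mean_discounted_qalys),
                            icer_lab)
      raw[[labels[k]]] <- c(out$mean_discounted_cost, out$crc_cases_per_1e5,
                            out$crc_deaths_per_1e5, out$mean_discounted_qalys,
                            if (cmp$verdict == "ICER") cmp$icer else NA_real_)
    }
    attr(tab, "raw") <- raw
    grids[[grid_name]] <- tab
  }
  attr(grids, "manifest") <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (grid_name in names(grids)) {
      write_report_csv(grids[[grid_name]],
                       file.path(out_dir, paste0("grid_", grid_name, ".csv")),
                       manifest)
      utils::write.csv(attr(grids[[grid_name]], "raw"),
                       file.path(out_dir, paste0("grid_", grid_name, "_raw.csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest_json(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  grids
}

#' Run the PSA under a named uptake scenario
#'
#' Two uptake scenarios are predefined for the FIT-versus-TCS
#' comparison: `"realistic"` (40% FIT uptake, 70% follow-up colonoscopy
#' after a positive FIT, 20% primary colonoscopy uptake) and
#' `"optimistic"` (60% FIT, 70% follow-up, 60% primary colonoscopy).
#' The TCS-based strategy is the intervention (strategy A).
#'
#' @param params A `crc_parameters` object.
#' @param scenario `"realistic"`, `"optimistic"`, or a list
#'   `list(fit_uptake=, tcs_after_fit_uptake=, primary_tcs_uptake=)`.
#' @param cfg A [psa_config()].
#' @param out_dir Optional output directory for the CE-plane CSV and
#'   summary JSON.
#' @return A `crc_psa_result` (see [run_psa()]).
#' @export
run_psa_scenario <- function(params, scenario = "realistic",
                             cfg = psa_config(), out_dir = NULL) {
  if (is.character(scenario)) {
    uptakes <- switch(scenario,
                      realistic = list(fit_uptake = 0.40, tcs_after_fit_uptake = 0.70,
                                       primary_tcs_uptake = 0.20),
                      optimistic = list(fit_uptake = 0.60, tcs_after_fit_uptake = 0.70,
                                        primary_tcs_uptake = 0.60),
                      stop("unknown scenario '", scenario,
                           "'; available: realistic, optimistic", call. = FALSE))
    label <- scenario
  } else {
    uptakes <- scenario
    label <- "custom"
  }
  st_tcs <- strategy_spec("TCS_based", primary_tcs_uptake = uptakes$primary_tcs_uptake)
  st_fit <- strategy_spec("FIT_based", fit_uptake = uptakes$fit_uptake,
                          tcs_after_fit_uptake = uptakes$tcs_after_fit_uptake)
  result <- run_psa(params, st_tcs, st_fit, cfg)
  result$scenario <- label
  result$uptakes <- uptakes
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ce_plane_export(result, file.path(out_dir, paste0("ce_plane_", label, ".csv")))
    manifest <- run_manifest(params, list(psa = unclass(cfg), uptakes = uptakes))
    summary <- c(result$summary, list(scenario = label,
                                      synthetic_parameters = manifest$synthetic_parameters,
                                      manifest_hash = manifest$config_hash))
    summary$quadrants <- as.list(summary$quadrants)
    jsonlite::write_json(summary, file.path(out_dir, paste0("psa_", label, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' Write fixture files for the pipeline
#'
#' Emits a synthetic parameter file and a sampled population CSV so
#' every stage of the pipeline can be exercised without external data.
#'
#' @param dir Output directory.
#' @param seed Seed for [synthesize_parameters()] and the population.
#' @param n_individuals Size of the fixture population.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, seed = 1L, n_individuals = 1000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- synthesize_parameters(seed)
  params_path <- file.path(dir, "parameters.json")
  write_parameters(p, params_path)
  pop <- sample_population(population_spec(n_individuals, seed = seed))
  pop_path <- file.path(dir, "population.csv")
  utils::write.csv(pop, pop_path, row.names = FALSE)
  invisible(c(params = params_path, population = pop_path))
}
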