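#' Read and validate a YAML run configuration
#'
#' A run config names one scenario family and overrides any of its
#' parameters. Recognised top-level keys: `scenario` (one of `"simulate"`,
#' `"area"`, `"spread"`, `"sample_size"`, `"patchy"`, `"realistic"`),
#' `seed`, `population` (keys `n_individuals`, `side`, `shift_south`, `disp_sdlog`,
#' `meanlogs`) and `design` (scenario-specific keys, matching the
#' corresponding config constructor's arguments). Unknown keys anywhere are
#' rejected with a field-level message before any computation.
#'
#' @param path Path to a YAML file.
#' @return A validated `"run_config"` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenarios <- c("simulate", "area", "spread", "sample_size", "patchy",
                 "realistic")
  check_keys <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(unknown, collapse = ", ")))
    }
  }
  check_keys(cfg, c("scenario", "seed", "population", "design"), "top level")
  if (is.null(cfg$scenario) || !cfg$scenario %in% scenarios) {
    stop("config must set scenario to one of: ",
         paste(scenarios, collapse = ", "))
  }
  check_keys(cfg$population,
             c("n_individuals", "side", "shift_south", "disp_sdlog", "meanlogs"),
             "population")
  design_keys <- switch(
    cfg$scenario,
    simulate = c("disp_meanlog"),
    area = c("area_sides", "n_sample", "n_replicates"),
    spread = c("site_side", "spacings", "n_sample", "n_replicates"),
    sample_size = c("sizes", "n_replicates"),
    patchy = c("patch_side", "per_patch_n", "area_fracs", "n_sample",
               "n_replicates"),
    realistic = c("fixtures", "bandwidths", "ks", "n_individuals", "n_sample",
                  "n_replicates", "grid_nx", "grid_ny")
  )
  check_keys(cfg$design, design_keys, paste0("design (", cfg$scenario, ")"))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

config_population <- function(cfg) {
  pd <- population_defaults()
  p <- cfg$population
  if (!is.null(p$n_individuals)) pd$n <- as.integer(p$n_individuals)
  if (!is.null(p$side)) pd$rect <- rect(0, 0, p$side, p$side)
  if (!is.null(p$shift_south)) pd$shift_south <- p$shift_south
  if (!is.null(p$disp_sdlog)) pd$disp_sdlog <- p$disp_sdlog
  if (!is.null(p$meanlogs)) pd$meanlogs <- unlist(p$meanlogs)
  pd
}

provenance <- function(cfg, extra = list()) {
  c(list(
    package = "mantelmc",
    version = as.character(utils::packageVersion("mantelmc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    scenario = cfg$scenario,
    seed = cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC")
  ), extra)
}

#' Simulate a population from a config and write the individuals table
#'
#' Writes `individuals.csv` (see [write_individuals()]) and a
#' `provenance.json` sidecar recording parameters, seed and package
#' version.
#'
#' @param config Path to a YAML config (scenario `"simulate"`) or a
#'   `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Path to the individuals CSV, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  pd <- config_population(cfg)
  mu <- if (!is.null(cfg$design$disp_meanlog)) cfg$design$disp_meanlog else
    pd$meanlogs[["low"]]
  pop <- simulate_breeding_uniform(pd$n, pd$rect, seed = cfg$seed)
  if (pd$n > 0) {
    pop <- apply_migration(pop, migration_params(
      pd$shift_south, mu, pd$disp_sdlog, seed = split_seed(cfg$seed, 1L)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out_dir, "individuals.csv")
  write_individuals(pop, csv)
  jsonlite::write_json(
    provenance(cfg, list(n = pd$n, disp_meanlog = mu,
                         disp_sdlog = pd$disp_sdlog,
                         shift_south = pd$shift_south)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(csv)
}

#' Run an experiment from a config and write results and summary tables
#'
#' Dispatches to the scenario's runner and writes `results.csv` (one
#' replicate record per row), `summary.csv` (one cell per row) and a
#' `provenance.json` sidecar.
#'
#' @param config Path to a YAML config or a `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return The replicate-record data frame, invisibly.
#' @export
cmd_experiment <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  pd <- config_population(cfg)
  d <- cfg$design
  base <- list(pop = pd, meanlogs = pd$meanlogs, master_seed = cfg$seed)
  override <- function(ctor, extra) {
    args <- c(base, extra[!vapply(extra, is.null, logical(1))])
    # realistic runner does not take a population block
    if (identical(cfg$scenario, "realistic")) {
      args$pop <- NULL
      args$meanlogs <- NULL
    }
    do.call(ctor, args)
  }
  records <- switch(
    cfg$scenario,
    area = run_area_experiment(override(area_experiment_config, list(
      area_sides = unlist(d$area_sides), n_sample = d$n_sample,
      n_replicates = d$n_replicates))),
    spread = run_spread_experiment(override(spread_experiment_config, list(
      site_side = d$site_side, spacings = unlist(d$spacings),
      n_sample = d$n_sample, n_replicates = d$n_replicates))),
    sample_size = run_sample_size_experiment(override(
      sample_size_experiment_config,
      list(sizes = unlist(d$sizes), n_replicates = d$n_replicates))),
    patchy = run_patchy_experiment(override(patchy_experiment_config, list(
      patch_side = d$patch_side, per_patch_n = d$per_patch_n,
      area_fracs = unlist(d$area_fracs), n_sample = d$n_sample,
      n_replicates = d$n_replicates))),
    realistic = run_realistic_experiment(override(
      realistic_experiment_config,
      list(fixtures = d$fixtures, bandwidths = unlist(d$bandwidths),
           ks = unlist(d$ks), n = d$n_individuals, n_sample = d$n_sample,
           n_replicates = d$n_replicates, grid_nx = d$grid_nx,
           grid_ny = d$grid_ny))),
    stop("scenario '", cfg$scenario, "' is not an experiment")
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_replicates(records),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(provenance(cfg),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(records)
}

#' Compute a Mantel score from an individuals CSV
#'
#' Reads an individuals table (optionally restricted to ids listed one per
#' line in `ids_file`), computes the Mantel correlation between breeding
#' and non-breeding distances and, if requested, a permutation p-value.
#'
#' @param individuals_csv Path to a CSV written by [write_individuals()].
#' @param ids_file Optional path to a file of ids, one per line.
#' @param n_perm Number of permutations (0 = statistic only).
#' @param seed Integer seed for the permutation stream.
#' @param out Optional path for a one-row result CSV.
#' @return A `mantel_result`.
#' @export
cmd_mantel <- function(individuals_csv, ids_file = NULL, n_perm = 0L,
                       seed = 1L, out = NULL) {
  pop <- read_individuals(individuals_csv)
  ids <- if (!is.null(ids_file)) {
    as.integer(readLines(ids_file))
  } else {
    pop$id
  }
  rows <- match(ids, pop$id)
  if (anyNA(rows)) stop("ids file contains ids not present in the table")
  D1 <- stats::dist(cbind(pop$breed_x[rows], pop$breed_y[rows]))
  D2 <- stats::dist(cbind(pop$nonbreed_x[rows], pop$nonbreed_y[rows]))
  res <- mantel_permutation_test(D1, D2, n_perm = n_perm, seed = seed)
  if (!is.null(out)) {
    utils::write.csv(as.data.frame(res), out, row.names = FALSE)
  }
  res
}
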