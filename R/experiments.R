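#' Experiment configurations
#'
#' Each constructor captures the study conditions of one scenario family:
#' the population parameters, the design levels, the replicate count (100
#' in the study) and a master seed from which every stream is derived via
#' [split_seed()]. One population is generated per connectivity level and
#' reused across replicates, so that replicate variation reflects sampling
#' alone; set `fresh_population_per_replicate = TRUE` to regenerate instead.
#'
#' @param area_sides Side lengths of the centred square sampling areas.
#' @param n_sample Individuals marked per replicate.
#' @param n_replicates Replicates per cell.
#' @param pop Population geometry, as [population_defaults()].
#' @param meanlogs Named vector of displacement log-means (connectivity
#'   levels).
#' @param master_seed Master seed.
#' @param fresh_population_per_replicate Regenerate the population for each
#'   replicate instead of reusing one per connectivity level.
#' @return A config list of class `"experiment_config"`.
#' @name experiment_configs
NULL

new_config <- function(scenario, fields) {
  structure(c(list(scenario = scenario), fields),
            class = "experiment_config")
}

#' @rdname experiment_configs
#' @export
area_experiment_config <- function(area_sides = c(small = 1200, medium = 3000,
                                                  large = 4800),
                                   n_sample = 200L, n_replicates = 100L,
                                   pop = population_defaults(),
                                   meanlogs = pop$meanlogs, master_seed = 1L,
                                   fresh_population_per_replicate = FALSE) {
  new_config("area", list(area_sides = area_sides, n_sample = n_sample,
                          n_replicates = n_replicates, pop = pop,
                          meanlogs = meanlogs, master_seed = master_seed,
                          fresh_pop = fresh_population_per_replicate))
}

#' @rdname experiment_configs
#' @param site_side Side of each spread site.
#' @param spacings Centre-to-centre spacings of the 3 x 3 grid.
#' @export
spread_experiment_config <- function(site_side = 600,
                                     spacings = c(low = 660, medium = 1500,
                                                  high = 2520),
                                     n_sample = 200L, n_replicates = 100L,
                                     pop = population_defaults(),
                                     meanlogs = pop$meanlogs, master_seed = 1L,
                                     fresh_population_per_replicate = FALSE) {
  new_config("spread", list(site_side = site_side, spacings = spacings,
                            n_sample = n_sample, n_replicates = n_replicates,
                            pop = pop, meanlogs = meanlogs,
                            master_seed = master_seed,
                            fresh_pop = fresh_population_per_replicate))
}

#' @rdname experiment_configs
#' @param sizes Sample sizes drawn from the whole breeding range.
#' @export
sample_size_experiment_config <- function(sizes = c(10L, 50L, 100L, 1000L,
                                                    2500L, 5000L),
                                          n_replicates = 100L,
                                          pop = population_defaults(),
                                          meanlogs = pop$meanlogs,
                                          master_seed = 1L) {
  new_config("sample_size", list(sizes = sizes, n_replicates = n_replicates,
                                 pop = pop, meanlogs = meanlogs,
                                 master_seed = master_seed))
}

#' @rdname experiment_configs
#' @param patch_side Side of each of the four corner patches.
#' @param per_patch_n Individuals simulated per patch before restriction.
#' @param area_fracs Sampling-area side as a fraction of the patch side,
#'   one per size level.
#' @export
patchy_experiment_config <- function(patch_side = 1500,
                                     per_patch_n = 2500L,
                                     area_fracs = c(small = 0.5, medium = 0.75,
                                                    large = 1.0),
                                     n_sample = 200L, n_replicates = 100L,
                                     pop = population_defaults(),
                                     meanlogs = pop$meanlogs,
                                     master_seed = 1L) {
  new_config("patchy", list(patch_side = patch_side, per_patch_n = per_patch_n,
                            area_fracs = area_fracs, n_sample = n_sample,
                            n_replicates = n_replicates, pop = pop,
                            meanlogs = meanlogs, master_seed = master_seed))
}

#' @rdname experiment_configs
#' @param fixtures Names of bundled range fixtures to run.
#' @param bandwidths Longitudinal-rank bandwidths (one per connectivity
#'   level; the study values 1000/13000/25000 correspond to n = 50,000).
#' @param ks Numbers of sites drawn from the 20-site pool.
#' @param n Individuals per season.
#' @param field Gaussian-field parameter template (its seed is re-derived).
#' @param grid_nx,grid_ny Coarse-grid resolution for site selection.
#' @param compute_zone_truth Also compute a per-replicate zone truth over
#'   the bounding box of the selected sites (off by default: the realistic
#'   comparisons in the study are against the whole-population truth).
#' @export
realistic_experiment_config <- function(fixtures = c("wide", "compact",
                                                     "elongated"),
                                        bandwidths = c(high = 1000L,
                                                       medium = 13000L,
                                                       low = 25000L),
                                        ks = 3:20, n = 50000L,
                                        n_sample = 200L, n_replicates = 100L,
                                        field = gaussian_field_params(),
                                        grid_nx = 15L, grid_ny = 15L,
                                        compute_zone_truth = FALSE,
                                        master_seed = 1L) {
  new_config("realistic", list(fixtures = fixtures, bandwidths = bandwidths,
                               ks = ks, n = as.integer(n), n_sample = n_sample,
                               n_replicates = n_replicates, field = field,
                               grid_nx = grid_nx, grid_ny = grid_ny,
                               compute_zone_truth = compute_zone_truth,
                               master_seed = master_seed))
}

level_names <- function(x) {
  if (!is.null(names(x)) && all(nzchar(names(x)))) names(x) else
    as.character(x)
}

replicate_record <- function(scenario, connectivity, disp_meanlog,
                             design_level, replicate, r_sample, r_zone,
                             r_global, n_sample, seed,
                             k_sites = NA_integer_,
                             site_centroid_mean_dist = NA_real_) {
  data.frame(
    scenario = scenario, connectivity = connectivity,
    disp_meanlog = disp_meanlog, design_level = design_level,
    replicate = as.integer(replicate),
    r_sample = r_sample, r_zone_truth = r_zone, r_global_truth = r_global,
    bias_zone = r_sample - r_zone, bias_global = r_sample - r_global,
    n_sample = as.integer(n_sample), k_sites = as.integer(k_sites),
    site_centroid_mean_dist = site_centroid_mean_dist,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
}

simulate_level_population <- function(pop, mu, seed) {
  p <- simulate_breeding_uniform(pop$n, pop$rect, seed = seed)
  apply_migration(p, migration_params(pop$shift_south, mu, pop$disp_sdlog,
                                      seed = split_seed(seed, 1L)))
}

#' Run the single-area experiment
#'
#' For each connectivity level, one population is simulated and its global
#' truth computed; for each area size the zone truth (all individuals
#' breeding inside the area) is computed once, and each replicate marks
#' `n_sample` individuals at random within the area and scores them.
#'
#' @param config An [area_experiment_config()].
#' @return A data frame of replicate records (one simulated study per row).
#' @export
run_area_experiment <- function(config) {
  stopifnot(identical(config$scenario, "area"))
  center <- rect_centroid(config$pop$rect)
  levels <- level_names(config$meanlogs)
  sizes <- level_names(config$area_sides)
  out <- vector("list", 0)
  for (li in seq_along(config$meanlogs)) {
    mu <- config$meanlogs[[li]]
    pop <- simulate_level_population(config$pop, mu,
                                     split_seed(config$master_seed, 1L, li))
    r_global <- global_truth_score(pop)
    for (si in seq_along(config$area_sides)) {
      area <- centred_square(center, config$area_sides[[si]])
      r_zone <- zone_truth_score(pop, area)
      design <- area_design(area, config$n_sample)
      for (rep in seq_len(config$n_replicates)) {
        seed <- split_seed(config$master_seed, 2L, li, si, rep)
        if (isTRUE(config$fresh_pop)) {
          pop <- simulate_level_population(config$pop, mu,
                                           split_seed(seed, 3L))
          r_global <- global_truth_score(pop)
          r_zone <- zone_truth_score(pop, area)
        }
        res <- sample_area(pop, design, seed)
        out[[length(out) + 1L]] <- replicate_record(
          "area", levels[li], mu, sizes[si], rep,
          score_sample(pop, res$ids), r_zone, r_global,
          config$n_sample, seed)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the spread (3 x 3 grid) experiment
#'
#' As [run_area_experiment()], but marking across nine sites whose spacing
#' sets the design level; the zone is the bounding rectangle of the grid.
#'
#' @param config A [spread_experiment_config()].
#' @return A data frame of replicate records.
#' @export
run_spread_experiment <- function(config) {
  stopifnot(identical(config$scenario, "spread"))
  center <- rect_centroid(config$pop$rect)
  levels <- level_names(config$meanlogs)
  spreads <- level_names(config$spacings)
  out <- vector("list", 0)
  for (li in seq_along(config$meanlogs)) {
    mu <- config$meanlogs[[li]]
    pop <- simulate_level_population(config$pop, mu,
                                     split_seed(config$master_seed, 1L, li))
    r_global <- global_truth_score(pop)
    for (si in seq_along(config$spacings)) {
      design <- spread_design(center, config$site_side, config$spacings[[si]],
                              config$n_sample)
      r_zone <- zone_truth_score(pop, rect_bbox(design$sites))
      for (rep in seq_len(config$n_replicates)) {
        seed <- split_seed(config$master_seed, 2L, li, si, rep)
        res <- sample_spread_grid(pop, design, seed)
        out[[length(out) + 1L]] <- replicate_record(
          "spread", levels[li], mu, spreads[si], rep,
          score_sample(pop, res$ids), r_zone, r_global,
          config$n_sample, seed,
          site_centroid_mean_dist = res$site_centroid_mean_dist)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the sample-size experiment
#'
#' Random marking from the entire breeding range at each sample size; the
#' zone is the whole range, so the zone truth equals the global truth.
#'
#' @param config A [sample_size_experiment_config()].
#' @return A data frame of replicate records.
#' @export
run_sample_size_experiment <- function(config) {
  stopifnot(identical(config$scenario, "sample_size"))
  levels <- level_names(config$meanlogs)
  out <- vector("list", 0)
  for (li in seq_along(config$meanlogs)) {
    mu <- config$meanlogs[[li]]
    pop <- simulate_level_population(config$pop, mu,
                                     split_seed(config$master_seed, 1L, li))
    r_global <- global_truth_score(pop)
    for (si in seq_along(config$sizes)) {
      size <- config$sizes[[si]]
      design <- area_design(config$pop$rect, size)
      for (rep in seq_len(config$n_replicates)) {
        seed <- split_seed(config$master_seed, 2L, li, si, rep)
        res <- sample_area(pop, design, seed)
        out[[length(out) + 1L]] <- replicate_record(
          "sample_size", levels[li], mu, as.character(size), rep,
          score_sample(pop, res$ids), r_global, r_global, size, seed)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the patchy-population experiment
#'
#' Four corner sub-populations restricted to four non-breeding regions;
#' marking uses a centred sampling area within each patch, with the area
#' side varied as a fraction of the patch side. The zone is the union of
#' the four sampling areas.
#'
#' @param config A [patchy_experiment_config()].
#' @return A data frame of replicate records.
#' @export
run_patchy_experiment <- function(config) {
  stopifnot(identical(config$scenario, "patchy"))
  pd <- config$pop
  layout <- patchy_layout(
    breed_patches = corner_squares(pd$rect, config$patch_side),
    nonbreed_regions = corner_squares(
      rect(pd$rect$xmin, pd$rect$ymin - pd$shift_south,
           pd$rect$xmax, pd$rect$ymax - pd$shift_south),
      config$patch_side),
    per_patch_n = config$per_patch_n)
  levels <- level_names(config$meanlogs)
  sizes <- level_names(config$area_fracs)
  out <- vector("list", 0)
  for (li in seq_along(config$meanlogs)) {
    mu <- config$meanlogs[[li]]
    params <- migration_params(pd$shift_south, mu, pd$disp_sdlog)
    pop <- simulate_patchy_population(layout, params,
                                      seed = split_seed(config$master_seed,
                                                        1L, li))
    r_global <- global_truth_score(pop)
    for (si in seq_along(config$area_fracs)) {
      side <- config$area_fracs[[si]] * config$patch_side
      areas <- lapply(layout$breed_patches,
                      function(p) centred_square(rect_centroid(p), side))
      r_zone <- zone_truth_score(pop, areas)
      for (rep in seq_len(config$n_replicates)) {
        seed <- split_seed(config$master_seed, 2L, li, si, rep)
        res <- sample_patchy(pop, areas, config$n_sample, seed)
        out[[length(out) + 1L]] <- replicate_record(
          "patchy", levels[li], mu, sizes[si], rep,
          score_sample(pop, res$ids), r_zone, r_global,
          config$n_sample, seed)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the realistic-range discrete-site experiment
#'
#' For each bundled range fixture and rank-match bandwidth, one spatially
#' clustered population is built; its 20 top-density cells form the site
#' pool, and each replicate draws k sites and marks 200 individuals across
#' them, recording the Mantel score and the mean distance between selected
#' site centroids.
#'
#' @param config A [realistic_experiment_config()].
#' @return A data frame of replicate records (`design_level` is the
#'   fixture name, `k_sites` the number of sites).
#' @export
run_realistic_experiment <- function(config) {
  stopifnot(identical(config$scenario, "realistic"))
  bw_levels <- level_names(config$bandwidths)
  out <- vector("list", 0)
  for (fi in seq_along(config$fixtures)) {
    fixture <- config$fixtures[[fi]]
    breed_range <- range_fixture(fixture, "breeding")
    nonbreed_range <- range_fixture(fixture, "nonbreeding")
    grid <- coarse_grid(polygon_bbox(breed_range), config$grid_nx,
                        config$grid_ny)
    for (bi in seq_along(config$bandwidths)) {
      b <- config$bandwidths[[bi]]
      field <- config$field
      field$seed <- split_seed(config$master_seed, 1L, fi, bi)
      pop <- build_realistic_population(
        breed_range, nonbreed_range, field, config$n,
        rank_match_params(b, seed = split_seed(config$master_seed, 2L, fi, bi)))
      r_global <- global_truth_score(pop)
      pool <- select_top_density_cells(cbind(pop$breed_x, pop$breed_y),
                                       grid, 20L)
      for (k in config$ks) {
        for (rep in seq_len(config$n_replicates)) {
          seed <- split_seed(config$master_seed, 3L, fi, bi, k, rep)
          res <- sample_sites(pop, site_design(pool, k, config$n_sample,
                                               seed = seed))
          r_zone <- if (isTRUE(config$compute_zone_truth)) {
            zone_truth_score(pop, res$zone)
          } else {
            NA_real_
          }
          out[[length(out) + 1L]] <- replicate_record(
            "realistic", bw_levels[bi], NA_real_, fixture, rep,
            score_sample(pop, res$ids), r_zone, r_global,
            config$n_sample, seed, k_sites = k,
            site_centroid_mean_dist = res$site_centroid_mean_dist)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Summarise replicate records
#'
#' Per (scenario, connectivity, design level, k): mean and SD (n - 1
#' denominator) of the Mantel scores, mean biases, and replicate count.
#'
#' @param records A replicate-record data frame from a runner.
#' @return A summary data frame, one row per cell.
#' @export
summarize_replicates <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  kk <- ifelse(is.na(records$k_sites), -1L, records$k_sites)  # NA-safe key
  key <- interaction(records$scenario, records$connectivity,
                     records$design_level, kk,
                     drop = TRUE, lex.order = TRUE)
  cells <- split(records, key)
  if (any(vapply(cells, nrow, integer(1)) < 2)) {
    stop("every summary cell needs at least 2 replicate records")
  }
  out <- do.call(rbind, lapply(cells, function(d) {
    data.frame(
      scenario = d$scenario[1], connectivity = d$connectivity[1],
      design_level = d$design_level[1], k_sites = d$k_sites[1],
      mean_r = mean(d$r_sample), sd_r = stats::sd(d$r_sample),
      mean_bias_zone = mean(d$bias_zone),
      mean_bias_global = mean(d$bias_global),
      n_replicates = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
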