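#' Default geometry of the abstract migratory population
#'
#' The simple scenarios place N individuals uniformly in a square breeding
#' range and translate them due south by a fixed shift before adding a
#' lognormal random displacement. The side length and shift are calibrated
#' so the weakest connectivity level (meanlog 7) yields a whole-population
#' Mantel correlation of about 0.33; the shift is twice the side, which
#' keeps the seasonal ranges disjoint even under large displacements.
#'
#' @return A list with elements `n` (10,000), `rect` (the 6000 x 6000
#'   breeding square), `shift_south` (12,000 map units), `disp_sdlog` (1)
#'   and `meanlogs` (named vector: high = 3, medium = 5, low = 7).
#' @export
population_defaults <- function() {
  list(
    n = 10000L,
    rect = rect(0, 0, 6000, 6000),
    shift_south = 12000,
    disp_sdlog = 1,
    meanlogs = c(high = 3, medium = 5, low = 7)
  )
}

#' Migration parameters
#'
#' Migration is a fixed due-south translation followed by a random
#' displacement: direction uniform on \[0, 360) degrees, distance lognormal
#' with log-scale mean `disp_meanlog` and log-scale SD `disp_sdlog`.
#' Larger `disp_meanlog` means larger random displacement relative to the
#' breeding range and hence weaker migratory connectivity; the three study
#' levels are 3 (high), 5 (medium) and 7 (low connectivity) with SD 1.
#'
#' @param shift_south Fixed southward translation, map units, >= 0.
#' @param disp_meanlog Log-scale mean of displacement distance.
#' @param disp_sdlog Log-scale SD of displacement distance, > 0.
#' @param seed Optional integer seed. When `NULL`, [apply_migration()] draws
#'   from the current RNG stream (used by composite simulators).
#' @return An object of class `"migration_params"`.
#' @export
migration_params <- function(shift_south, disp_meanlog, disp_sdlog = 1,
                             seed = NULL) {
  if (!is.finite(shift_south) || shift_south < 0) {
    stop("shift_south must be a finite non-negative number")
  }
  if (!is.finite(disp_sdlog) || disp_sdlog <= 0) {
    stop("disp_sdlog must be > 0")
  }
  structure(list(shift_south = shift_south, disp_meanlog = disp_meanlog,
                 disp_sdlog = disp_sdlog, seed = seed),
            class = "migration_params")
}

new_paired_population <- function(id, breed_x, breed_y,
                                  nonbreed_x = NA_real_,
                                  nonbreed_y = NA_real_) {
  df <- data.frame(id = as.integer(id), breed_x = breed_x, breed_y = breed_y,
                   nonbreed_x = rep_len(nonbreed_x, length(id)),
                   nonbreed_y = rep_len(nonbreed_y, length(id)))
  class(df) <- c("paired_population", "data.frame")
  df
}

#' @export
print.paired_population <- function(x, ...) {
  cat(sprintf("<paired_population: %d individuals%s>\n", nrow(x),
              if (all(is.na(x$nonbreed_x))) ", non-breeding unset" else ""))
  NextMethod()
}

#' Place breeding individuals uniformly within a rectangle
#'
#' Breeding x and y coordinates are drawn independently from bounded uniform
#' distributions, so that downstream variation in connectivity estimates
#' reflects sampling effects alone rather than heterogeneous spacing.
#'
#' @param n Number of individuals, >= 0.
#' @param rect Breeding range, a [rect()].
#' @param seed Integer seed; identical seeds give bit-identical populations.
#' @return A `paired_population` with non-breeding coordinates unset (`NA`).
#' @export
simulate_breeding_uniform <- function(n, rect = population_defaults()$rect,
                                      seed = 1L) {
  if (!is_rect(rect)) stop("rect must be a rect object")
  if (n < 0) stop("n must be >= 0")
  set.seed(seed)
  new_paired_population(
    id = seq_len(n),
    breed_x = stats::runif(n, rect$xmin, rect$xmax),
    breed_y = stats::runif(n, rect$ymin, rect$ymax)
  )
}

#' Apply the migration model to a breeding population
#'
#' Each individual is shifted a fixed distance due south and then displaced
#' by a random vector: direction uniform over the full circle, distance
#' lognormal on the log scale given by the parameters. The non-breeding
#' location is
#' `breed + (0, -shift_south) + d * (cos(theta), sin(theta))`.
#'
#' @param pop A `paired_population` with breeding coordinates set.
#' @param params A [migration_params()]. If `params$seed` is non-`NULL` the
#'   RNG is seeded with it; otherwise the current stream is used.
#' @return The population with non-breeding coordinates filled in.
#' @export
apply_migration <- function(pop, params) {
  stopifnot(inherits(pop, "paired_population"),
            inherits(params, "migration_params"))
  if (nrow(pop) > 0 && any(!is.finite(pop$breed_x))) {
    stop("breeding coordinates must be set before migration")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- nrow(pop)
  theta_deg <- stats::runif(n, 0, 360)
  d <- stats::rlnorm(n, meanlog = params$disp_meanlog,
                     sdlog = params$disp_sdlog)
  pop$nonbreed_x <- pop$breed_x + d * cospi(theta_deg / 180)
  pop$nonbreed_y <- pop$breed_y - params$shift_south + d * sinpi(theta_deg / 180)
  pop
}

#' Patchy population layout
#'
#' Four equal-sized breeding patches (sub-populations) and four equal-sized
#' non-breeding regions. Defaults place 1500 x 1500 squares at the corners
#' of the calibrated 6000 x 6000 breeding range, and matching regions at the
#' corresponding corners of the range translated south by the default shift.
#'
#' @param breed_patches List of exactly 4 disjoint equal-area [rect()]s.
#' @param nonbreed_regions List of exactly 4 equal-area [rect()]s.
#' @param per_patch_n Individuals simulated per breeding patch.
#' @return An object of class `"patchy_layout"`.
#' @export
patchy_layout <- function(breed_patches = NULL, nonbreed_regions = NULL,
                          per_patch_n = 2500L) {
  defaults <- population_defaults()
  if (is.null(breed_patches)) {
    breed_patches <- corner_squares(defaults$rect, side = 1500)
  }
  if (is.null(nonbreed_regions)) {
    shifted <- rect(defaults$rect$xmin, defaults$rect$ymin - defaults$shift_south,
                    defaults$rect$xmax, defaults$rect$ymax - defaults$shift_south)
    nonbreed_regions <- corner_squares(shifted, side = 1500)
  }
  stopifnot(length(breed_patches) == 4, length(nonbreed_regions) == 4,
            per_patch_n >= 0)
  areas_b <- vapply(breed_patches, rect_area, numeric(1))
  areas_n <- vapply(nonbreed_regions, rect_area, numeric(1))
  if (max(abs(areas_b - areas_b[1])) > 1e-9 * areas_b[1]) {
    stop("breeding patches must have equal areas")
  }
  if (max(abs(areas_n - areas_n[1])) > 1e-9 * areas_n[1]) {
    stop("non-breeding regions must have equal areas")
  }
  if (!rects_pairwise_disjoint(breed_patches)) {
    stop("breeding patches must be pairwise disjoint")
  }
  structure(list(breed_patches = breed_patches,
                 nonbreed_regions = nonbreed_regions,
                 per_patch_n = as.integer(per_patch_n)),
            class = "patchy_layout")
}

#' Four equal squares at the corners of a rectangle
#' @param r Enclosing `rect`.
#' @param side Side of each corner square.
#' @return List of 4 `rect`s (order: SW, SE, NW, NE).
#' @export
corner_squares <- function(r, side) {
  stopifnot(is_rect(r), side > 0,
            2 * side <= (r$xmax - r$xmin), 2 * side <= (r$ymax - r$ymin))
  list(
    rect(r$xmin, r$ymin, r$xmin + side, r$ymin + side),
    rect(r$xmax - side, r$ymin, r$xmax, r$ymin + side),
    rect(r$xmin, r$ymax - side, r$xmin + side, r$ymax),
    rect(r$xmax - side, r$ymax - side, r$xmax, r$ymax)
  )
}

#' Simulate a patchy migratory population
#'
#' Individuals are placed uniformly within each of four equal-sized breeding
#' patches, migrate under the shared migration model, and the population is
#' then restricted to individuals whose non-breeding location falls inside
#' one of the four non-breeding regions, yielding clearly delimited
#' sub-populations in both seasons.
#'
#' @param layout A [patchy_layout()].
#' @param params A [migration_params()] (its `seed`, if set, is ignored; the
#'   whole simulation runs from `seed`).
#' @param seed Integer seed for the entire simulation.
#' @return A restricted `paired_population`; ids refer to the pre-restriction
#'   enumeration and are preserved.
#' @export
simulate_patchy_population <- function(layout, params, seed = 1L) {
  stopifnot(inherits(layout, "patchy_layout"),
            inherits(params, "migration_params"))
  set.seed(seed)
  m <- layout$per_patch_n
  xs <- ys <- numeric(0)
  for (p in layout$breed_patches) {
    xs <- c(xs, stats::runif(m, p$xmin, p$xmax))
    ys <- c(ys, stats::runif(m, p$ymin, p$ymax))
  }
  pop <- new_paired_population(seq_along(xs), xs, ys)
  params$seed <- NULL  # keep the single RNG stream started by `seed`
  pop <- apply_migration(pop, params)
  restrict_to_nonbreeding_regions(pop, layout$nonbreed_regions)
}

#' Restrict a population to non-breeding regions
#'
#' Keeps exactly the individuals whose non-breeding point lies inside the
#' union of the given rectangles (closed boundaries); ids are preserved.
#' An empty result is allowed.
#'
#' @param pop A `paired_population` with non-breeding coordinates set.
#' @param regions List of `rect`s.
#' @return The restricted `paired_population`.
#' @export
restrict_to_nonbreeding_regions <- function(pop, regions) {
  stopifnot(inherits(pop, "paired_population"))
  if (nrow(pop) > 0 && any(is.na(pop$nonbreed_x))) {
    stop("non-breeding coordinates must be set before restriction")
  }
  keep <- rects_contain(regions, pop$nonbreed_x, pop$nonbreed_y)
  out <- pop[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_population", "data.frame")
  out
}

#' Write an individuals table
#'
#' CSV with header `id,breed_x,breed_y,nonbreed_x,nonbreed_y`, one row per
#' individual, coordinates printed at 17 significant digits so that
#' [read_individuals()] round-trips bit-exactly.
#'
#' @param pop A `paired_population`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_individuals <- function(pop, path) {
  stopifnot(inherits(pop, "paired_population"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c(
    "id,breed_x,breed_y,nonbreed_x,nonbreed_y",
    if (nrow(pop) > 0) {
      paste(pop$id, fmt(pop$breed_x), fmt(pop$breed_y),
            fmt(pop$nonbreed_x), fmt(pop$nonbreed_y), sep = ",")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an individuals table written by [write_individuals()]
#' @param path CSV file path.
#' @return A `paired_population`.
#' @export
read_individuals <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  required <- c("id", "breed_x", "breed_y", "nonbreed_x", "nonbreed_y")
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop("individuals file is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- utils::read.csv(path, colClasses = c("integer", rep("numeric", 4)))
  new_paired_population(df$id, df$breed_x, df$breed_y,
                        df$nonbreed_x, df$nonbreed_y)
}
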