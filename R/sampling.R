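#' Single-area marking design
#'
#' One rectangular sampling area centred within the breeding range, from
#' which a fixed number of individuals is marked at random. The study's
#' default marks 200 individuals.
#'
#' @param area Sampling rectangle.
#' @param n_sample Number of individuals to mark.
#' @return An object of class `"area_design"`.
#' @export
area_design <- function(area, n_sample = 200L) {
  stopifnot(is_rect(area), n_sample >= 1)
  structure(list(area = area, n_sample = as.integer(n_sample)),
            class = "area_design")
}

#' Nine-site spread marking design
#'
#' Nine equal square sites on a regular 3 x 3 grid centred at `center`,
#' with centre-to-centre `spacing`. Varying the spacing while holding site
#' size and sample size constant isolates the effect of sampling spread.
#'
#' @param center Grid centre `(x, y)`.
#' @param site_side Side of each square site.
#' @param spacing Centre-to-centre distance; must be >= `site_side` so the
#'   sites do not overlap.
#' @param n_sample Number of individuals to mark across the nine sites.
#' @return An object of class `"spread_design"` with a `sites` list of 9
#'   rectangles.
#' @export
spread_design <- function(center, site_side, spacing, n_sample = 200L) {
  stopifnot(site_side > 0, spacing >= site_side, n_sample >= 1)
  offsets <- c(-spacing, 0, spacing)
  sites <- list()
  for (dy in offsets) {
    for (dx in offsets) {
      sites <- c(sites, list(centred_square(center + c(dx, dy), site_side)))
    }
  }
  structure(list(sites = sites, spacing = spacing, site_side = site_side,
                 n_sample = as.integer(n_sample)),
            class = "spread_design")
}

#' Discrete-site marking design over a candidate pool
#'
#' A pool of 20 candidate sites (the top-density grid cells of a realistic
#' population); `k` of them are drawn at random and the sample is pooled
#' across the selected sites.
#'
#' @param pool List of exactly 20 candidate site rectangles.
#' @param k Number of sites to use (3-20 in the study; >= 1 accepted).
#' @param n_sample Number of individuals to mark.
#' @param seed Integer seed for site selection and marking.
#' @return An object of class `"site_design"`.
#' @export
site_design <- function(pool, k, n_sample = 200L, seed = 1L) {
  stopifnot(length(pool) == 20, k >= 1, k <= length(pool), n_sample >= 1)
  structure(list(pool = pool, k = as.integer(k),
                 n_sample = as.integer(n_sample), seed = as.integer(seed)),
            class = "site_design")
}

new_sample_result <- function(design, ids, zone, sites = NULL) {
  structure(list(
    design = design,
    ids = ids,
    zone = zone,
    sites = sites,
    site_centroid_mean_dist = if (!is.null(sites) && length(sites) >= 2) {
      mean_site_centroid_distance(sites)
    } else {
      NA_real_
    }
  ), class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("<sample_result: %s design, %d individuals%s>\n", x$design,
              length(x$ids),
              if (!is.na(x$site_centroid_mean_dist)) {
                sprintf(", mean site-centroid distance %.1f",
                        x$site_centroid_mean_dist)
              } else ""))
  invisible(x)
}

draw_from_pool <- function(pool_ids, n_sample, what) {
  if (length(pool_ids) < n_sample) {
    stop(sprintf(
      "insufficient individuals in %s: need %d, found %d (short by %d)",
      what, n_sample, length(pool_ids), n_sample - length(pool_ids)
    ))
  }
  sample(pool_ids, n_sample)
}

#' Mark individuals within a single area
#'
#' Draws `n_sample` ids uniformly without replacement from the individuals
#' whose breeding point lies inside the design's area. Only the breeding
#' location is constrained; non-breeding locations are never restricted by
#' any marking design.
#'
#' @param pop A `paired_population`.
#' @param design An [area_design()].
#' @param seed Integer seed.
#' @return A `sample_result` whose zone is the sampling area itself.
#' @export
sample_area <- function(pop, design, seed = 1L) {
  stopifnot(inherits(pop, "paired_population"), inherits(design, "area_design"))
  set.seed(seed)
  inside <- rect_contains(design$area, pop$breed_x, pop$breed_y)
  ids <- draw_from_pool(pop$id[inside], design$n_sample, "sampling area")
  new_sample_result("area", ids, zone = design$area)
}

#' Mark individuals across a 3 x 3 spread grid
#'
#' Pooled uniform draw across the union of the nine sites (no per-site
#' quota). The zone — the strict spatial extent of sampling — is the
#' axis-aligned bounding rectangle of the nine sites, i.e. the contiguous
#' extent spanned by the design.
#'
#' @param pop A `paired_population`.
#' @param design A [spread_design()].
#' @param seed Integer seed.
#' @return A `sample_result` with the site list and mean centroid distance.
#' @export
sample_spread_grid <- function(pop, design, seed = 1L) {
  stopifnot(inherits(pop, "paired_population"),
            inherits(design, "spread_design"))
  set.seed(seed)
  inside <- rects_contain(design$sites, pop$breed_x, pop$breed_y)
  ids <- draw_from_pool(pop$id[inside], design$n_sample, "spread sites")
  new_sample_result("spread", ids, zone = rect_bbox(design$sites),
                    sites = design$sites)
}

#' Mark individuals across four per-patch areas
#'
#' One rectangular sampling area centred within each breeding
#' sub-population; the draw is pooled across the union of the four areas.
#' The zone is the union of the four areas.
#'
#' @param pop A `paired_population` (typically patchy).
#' @param areas List of 4 sampling rectangles.
#' @param n_sample Number of individuals to mark.
#' @param seed Integer seed.
#' @return A `sample_result`.
#' @export
sample_patchy <- function(pop, areas, n_sample = 200L, seed = 1L) {
  stopifnot(inherits(pop, "paired_population"), length(areas) == 4)
  set.seed(seed)
  inside <- rects_contain(areas, pop$breed_x, pop$breed_y)
  ids <- draw_from_pool(pop$id[inside], n_sample, "patch sampling areas")
  new_sample_result("patchy", ids, zone = areas, sites = areas)
}

#' Coarse grid over a bounding box
#'
#' @param bbox A `rect` to cover.
#' @param nx,ny Cell counts (defaults 15 x 15).
#' @return An object of class `"coarse_grid"`.
#' @export
coarse_grid <- function(bbox, nx = 15L, ny = 15L) {
  stopifnot(is_rect(bbox), nx >= 1, ny >= 1)
  structure(list(bbox = bbox, nx = as.integer(nx), ny = as.integer(ny)),
            class = "coarse_grid")
}

grid_cell_index <- function(grid, x, y) {
  bb <- grid$bbox
  cx <- pmin(pmax(ceiling((x - bb$xmin) / (bb$xmax - bb$xmin) * grid$nx), 1L),
             grid$nx)
  cy <- pmin(pmax(ceiling((y - bb$ymin) / (bb$ymax - bb$ymin) * grid$ny), 1L),
             grid$ny)
  (cy - 1L) * grid$nx + cx  # row-major cell id
}

grid_cell_rect <- function(grid, cell) {
  bb <- grid$bbox
  dx <- (bb$xmax - bb$xmin) / grid$nx
  dy <- (bb$ymax - bb$ymin) / grid$ny
  cx <- (cell - 1L) %% grid$nx
  cy <- (cell - 1L) %/% grid$nx
  rect(bb$xmin + cx * dx, bb$ymin + cy * dy,
       bb$xmin + (cx + 1L) * dx, bb$ymin + (cy + 1L) * dy)
}

#' Select the highest-density grid cells as candidate sites
#'
#' Counts breeding points per cell of a coarse grid and returns the `k`
#' cells with the most individuals as site rectangles — mimicking the
#' logistical practice of sampling where the species is most abundant.
#' Ties are broken by row-major cell index for determinism.
#'
#' @param breed_pts n x 2 matrix of breeding coordinates.
#' @param grid A [coarse_grid()] covering the points.
#' @param k Number of cells to select.
#' @return List of `k` site rectangles, ordered by decreasing count.
#' @export
select_top_density_cells <- function(breed_pts, grid, k) {
  stopifnot(inherits(grid, "coarse_grid"), k >= 1)
  breed_pts <- as.matrix(breed_pts)
  cell <- grid_cell_index(grid, breed_pts[, 1], breed_pts[, 2])
  counts <- tabulate(cell, nbins = grid$nx * grid$ny)
  occupied <- sum(counts > 0)
  if (occupied < k) {
    stop(sprintf("only %d occupied cells, need %d", occupied, k))
  }
  top <- order(-counts, seq_along(counts))[seq_len(k)]
  lapply(top, function(c) grid_cell_rect(grid, c))
}

#' Mark individuals across k randomly selected discrete sites
#'
#' Draws `k` sites uniformly from the pool of 20, then marks `n_sample`
#' individuals pooled uniformly across the union of the selected sites.
#' If the selected sites hold too few individuals, sites are redrawn with a
#' derived sub-seed (up to 10 attempts) before failing. The zone is the
#' bounding rectangle of the selected sites.
#'
#' @param pop A `paired_population`.
#' @param design A [site_design()].
#' @return A `sample_result` carrying the selected sites and their mean
#'   pairwise centroid distance (`NA` for a single site).
#' @export
sample_sites <- function(pop, design) {
  stopifnot(inherits(pop, "paired_population"), inherits(design, "site_design"))
  for (attempt in seq_len(10L)) {
    set.seed(if (attempt == 1L) design$seed else
               split_seed(design$seed, 13L, attempt))
    sel <- design$pool[sample.int(length(design$pool), design$k)]
    inside <- rects_contain(sel, pop$breed_x, pop$breed_y)
    if (sum(inside) >= design$n_sample) {
      ids <- sample(pop$id[inside], design$n_sample)
      return(new_sample_result("sites", ids, zone = rect_bbox(sel),
                               sites = sel))
    }
  }
  stop(sprintf("could not find %d sites holding >= %d individuals in 10 attempts",
               design$k, design$n_sample))
}

#' Mean pairwise distance between site centroids
#'
#' Arithmetic mean of centroid-to-centroid distances over all unordered
#' site pairs — the design covariate that separates under- from
#' overestimation in the realistic scenarios.
#'
#' @param sites List of >= 2 site rectangles.
#' @return Mean distance in map units; `NA` with a warning for < 2 sites.
#' @export
mean_site_centroid_distance <- function(sites) {
  if (length(sites) < 2) {
    warning("mean centroid distance undefined for fewer than 2 sites")
    return(NA_real_)
  }
  centroids <- t(vapply(sites, rect_centroid, numeric(2)))
  mean(stats::dist(centroids))
}
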