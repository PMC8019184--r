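test_that("area sampling draws uniquely, in bounds, and reproducibly", {
  pop <- tiny_population(n = 500, side = 100, seed = 3)
  design <- area_design(rect(20, 20, 80, 80), n_sample = 50)
  res <- sample_area(pop, design, seed = 7)
  expect_length(res$ids, 50)
  expect_equal(anyDuplicated(res$ids), 0)
  rows <- match(res$ids, pop$id)
  expect_true(all(rect_contains(design$area, pop$breed_x[rows],
                                pop$breed_y[rows])))
  expect_identical(res$ids, sample_area(pop, design, seed = 7)$ids)

  # whole range, full population: identity sample
  all_res <- sample_area(pop, area_design(rect(0, 0, 100, 100), 500), seed = 1)
  expect_setequal(all_res$ids, pop$id)

  expect_error(sample_area(pop, area_design(rect(0, 0, 1, 1), 10), seed = 1),
               "insufficient individuals")
})

test_that("inclusion probabilities are uniform across individuals", {
  pop <- tiny_population(n = 100, side = 10, seed = 5)
  design <- area_design(rect(0, 0, 10, 10), n_sample = 10)
  counts <- integer(100)
  for (i in 1:2000) {
    ids <- sample_area(pop, design, seed = 10000 + i)$ids
    counts[ids] <- counts[ids] + 1L
  }
  freq <- counts / 2000
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_true(all(abs(freq - 0.1) < 4 * se))
})

test_that("spread grids are regular, disjoint, and pooled-sampled", {
  design <- spread_design(c(0, 0), site_side = 10, spacing = 25,
                          n_sample = 60)
  expect_length(design$sites, 9)
  centroids <- t(vapply(design$sites, rect_centroid, numeric(2)))
  expect_setequal(centroids[, 1], c(-25, 0, 25))
  expect_true(rects_pairwise_disjoint(design$sites))

  pop <- tiny_population(n = 2000, side = 100, seed = 8)
  shifted <- spread_design(c(50, 50), 10, 25, 60)
  res <- sample_spread_grid(pop, shifted, seed = 2)
  rows <- match(res$ids, pop$id)
  expect_true(all(rects_contain(shifted$sites, pop$breed_x[rows],
                                pop$breed_y[rows])))
  # zone is the bounding rectangle of the grid
  expect_equal(res$zone$xmax - res$zone$xmin, 2 * 25 + 10)
  expect_equal(res$site_centroid_mean_dist,
               mean_site_centroid_distance(shifted$sites))

  expect_error(spread_design(c(0, 0), 10, 5, 10), "spacing")
})

test_that("patchy sampling allocates proportionally to in-area counts", {
  layout <- patchy_layout(per_patch_n = 500)
  params <- migration_params(population_defaults()$shift_south, 3, 1)
  pop <- simulate_patchy_population(layout, params, seed = 6)
  areas <- lapply(layout$breed_patches,
                  function(p) centred_square(rect_centroid(p), 1000))
  res <- sample_patchy(pop, areas, n_sample = 200, seed = 4)
  expect_length(res$ids, 200)
  rows <- match(res$ids, pop$id)
  expect_true(all(rects_contain(areas, pop$breed_x[rows], pop$breed_y[rows])))

  # expected allocation proportional to in-area population
  in_area <- vapply(areas, function(a) {
    sum(rect_contains(a, pop$breed_x, pop$breed_y))
  }, numeric(1))
  alloc <- vapply(areas, function(a) {
    sum(rect_contains(a, pop$breed_x[rows], pop$breed_y[rows]))
  }, numeric(1))
  p <- in_area / sum(in_area)
  se <- sqrt(200 * p * (1 - p))
  expect_true(all(abs(alloc - 200 * p) < 4 * se + 1))
})

test_that("top-density cells match brute-force counting", {
  set.seed(30)
  pts <- cbind(runif(3000, 0, 30), runif(3000, 0, 30))
  grid <- coarse_grid(rect(0, 0, 30, 30), nx = 6, ny = 6)
  sites <- select_top_density_cells(pts, grid, 5)
  counts <- vapply(sites, function(s) {
    sum(rect_contains(s, pts[, 1], pts[, 2]))
  }, numeric(1))
  # brute-force per-cell counts over the full grid
  all_counts <- numeric(36)
  for (cy in 1:6) {
    for (cx in 1:6) {
      cell <- rect((cx - 1) * 5, (cy - 1) * 5, cx * 5, cy * 5)
      all_counts[(cy - 1) * 6 + cx] <- sum(rect_contains(cell, pts[, 1],
                                                         pts[, 2]))
    }
  }
  expect_equal(sort(counts, decreasing = TRUE),
               sort(all_counts, decreasing = TRUE)[1:5],
               tolerance = 1e-9)

  one_cell <- select_top_density_cells(cbind(rep(1, 10), rep(1, 10)),
                                       grid, 1)
  expect_true(rect_contains(one_cell[[1]], 1, 1))
  expect_error(select_top_density_cells(cbind(1, 1), grid, 3),
               "occupied")
})

test_that("site centroid distances follow the pairwise mean", {
  s <- function(x, y) centred_square(c(x, y), 1)
  expect_equal(mean_site_centroid_distance(list(s(0, 0), s(10, 0))), 10)
  expect_equal(mean_site_centroid_distance(list(s(0, 0), s(3, 0), s(0, 4))),
               (3 + 4 + 5) / 3)
  # equilateral triangle, side 7
  expect_equal(mean_site_centroid_distance(
    list(s(0, 0), s(7, 0), s(3.5, 7 * sqrt(3) / 2))), 7)
  # random layout vs explicit pair enumeration
  set.seed(9)
  sites <- lapply(1:5, function(i) centred_square(runif(2, 0, 100), 2))
  cents <- t(vapply(sites, rect_centroid, numeric(2)))
  acc <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    acc <- c(acc, sqrt(sum((cents[i, ] - cents[j, ])^2)))
  }
  expect_equal(mean_site_centroid_distance(sites), mean(acc))
  expect_warning(mean_site_centroid_distance(list(s(0, 0))), "undefined")
})

test_that("k-of-20 site sampling honours the pool and records distances", {
  pop <- tiny_population(n = 5000, side = 100, seed = 44)
  grid <- coarse_grid(rect(0, 0, 100, 100), nx = 10, ny = 10)
  pool <- select_top_density_cells(cbind(pop$breed_x, pop$breed_y), grid, 20)
  res <- sample_sites(pop, site_design(pool, k = 4, n_sample = 50, seed = 5))
  expect_length(res$sites, 4)
  expect_length(res$ids, 50)
  rows <- match(res$ids, pop$id)
  expect_true(all(rects_contain(res$sites, pop$breed_x[rows],
                                pop$breed_y[rows])))
  expect_false(is.na(res$site_centroid_mean_dist))
  res2 <- sample_sites(pop, site_design(pool, k = 4, n_sample = 50, seed = 5))
  expect_identical(res$ids, res2$ids)

  single <- sample_sites(pop, site_design(pool, k = 1, n_sample = 5, seed = 2))
  expect_true(is.na(single$site_centroid_mean_dist))
})
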