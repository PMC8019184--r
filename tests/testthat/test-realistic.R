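test_that("bundled range fixtures load with sane geometry", {
  for (shape in c("wide", "compact", "elongated")) {
    b <- range_fixture(shape, "breeding")
    n <- range_fixture(shape, "nonbreeding")
    bb <- polygon_bbox(b); nb <- polygon_bbox(n)
    expect_gt(bb$ymin, nb$ymax)  # breeding north of non-breeding, disjoint
  }
  wide <- polygon_bbox(range_fixture("wide", "breeding"))
  comp <- polygon_bbox(range_fixture("compact", "breeding"))
  el <- polygon_bbox(range_fixture("elongated", "breeding"))
  expect_gt(rect_area(wide), rect_area(comp))
  aspect <- function(r) (r$xmax - r$xmin) / (r$ymax - r$ymin)
  expect_gt(aspect(el), 2 * aspect(wide))
})

test_that("point-in-polygon handles holes and matches hand cases", {
  outer <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)
  hole <- matrix(c(4, 4, 6, 4, 6, 6, 4, 6), ncol = 2, byrow = TRUE)
  poly <- range_polygon(list(outer, hole))
  expect_identical(
    point_in_polygon(poly, c(1, 5, 7, 11, 5), c(1, 5, 5, 5, 3)),
    c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(range_polygon(list(matrix(c(0, 0, 1, 1), 2, 2))), "vertices")
})

test_that("GeoJSON reader parses Polygon and MultiPolygon", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"MultiPolygon","coordinates":[',
    '[[[0,0],[2,0],[2,2],[0,2],[0,0]]],',
    '[[[5,0],[7,0],[7,2],[5,2],[5,0]]]]}'), path)
  poly <- read_range_polygon(path, season = "breeding")
  expect_length(poly$rings, 2)
  expect_identical(point_in_polygon(poly, c(1, 6, 3.5), c(1, 1, 1)),
                   c(TRUE, TRUE, FALSE))
})

test_that("individuals are distributed inside the polygon by cell weight", {
  poly <- square_polygon(0, 0, 10, 10)
  surf <- generate_gaussian_field(
    gaussian_field_params(grid_nx = 20, grid_ny = 20, seed = 9))
  pts <- distribute_individuals(surf, poly, 5000, seed = 2)
  expect_equal(nrow(pts), 5000)
  expect_true(all(point_in_polygon(poly, pts[, 1], pts[, 2])))

  # single non-zero cell concentrates every individual there
  one <- structure(list(weights = matrix(c(rep(0, 24), 1), 5, 5),
                        origin = c(0, 0), cell_dx = 1, cell_dy = 1),
                   class = "density_surface")
  pts1 <- distribute_individuals(one, poly, 200, seed = 3)
  expect_true(all(pts1[, 1] >= 8 & pts1[, 2] >= 8))

  # 2:1 weights: multinomial expectation over two cells
  two <- structure(list(weights = matrix(c(1, 0.5), 1, 2),
                        origin = c(0, 0), cell_dx = 5, cell_dy = 10),
                   class = "density_surface")
  pts2 <- distribute_individuals(two, poly, 30000, seed = 4)
  n_left <- sum(pts2[, 1] < 5)
  se <- sqrt(30000 * (2 / 3) * (1 / 3))
  expect_lt(abs(n_left - 30000 * 2 / 3), 4 * se)

  none <- structure(list(weights = matrix(0, 5, 5), origin = c(0, 0),
                         cell_dx = 1, cell_dy = 1),
                    class = "density_surface")
  expect_error(distribute_individuals(none, poly, 10, seed = 1),
               "all cell weights")
})

test_that("rank matching is a bijection within the bandwidth window", {
  rank_of <- function(pts) {
    o <- order(pts[, 1], pts[, 2], seq_len(nrow(pts)))
    r <- integer(nrow(pts)); r[o] <- seq_len(nrow(pts)); r
  }
  for (case in 1:6) {
    set.seed(case)
    n <- sample(50:400, 1)
    b <- sample(c(0L, 1L, 5L, n %/% 4, n), 1)
    bp <- cbind(runif(n), runif(n)); np <- cbind(runif(n), runif(n))
    pp <- match_by_longitudinal_rank(bp, np, rank_match_params(b, seed = case))
    key <- paste(pp$nonbreed_x, pp$nonbreed_y)
    expect_equal(anyDuplicated(key), 0)
    nb_rank <- rank_of(np)[match(key, paste(np[, 1], np[, 2]))]
    expect_true(all(abs(nb_rank - rank_of(bp)) <= b))
    # determinism
    pp2 <- match_by_longitudinal_rank(bp, np, rank_match_params(b, seed = case))
    expect_identical(pp, pp2)
  }
  expect_error(
    match_by_longitudinal_rank(cbind(1:3, 1:3), cbind(1:4, 1:4),
                               rank_match_params(1, seed = 1)),
    "equal size")
})

test_that("zero bandwidth is the longitude-order-preserving bijection", {
  set.seed(12)
  bp <- cbind(runif(40), runif(40)); np <- cbind(runif(40), runif(40))
  pp <- match_by_longitudinal_rank(bp, np, rank_match_params(0, seed = 1))
  expect_equal(stats::cor(rank(pp$breed_x), rank(pp$nonbreed_x),
                          method = "spearman"), 1)
})

test_that("full-bandwidth matching behaves like a uniform permutation", {
  # exhaustive expectation of the mean absolute rank displacement at n = 8
  n <- 8
  exact <- mean(vapply(all_perms(n), function(p) {
    mean(abs(p - seq_len(n)))
  }, numeric(1)))
  set.seed(3)
  obs <- replicate(50, {
    bp <- cbind(runif(n), runif(n)); np <- cbind(runif(n), runif(n))
    pp <- match_by_longitudinal_rank(bp, np,
                                     rank_match_params(n, seed = sample.int(1e6, 1)))
    mean(abs(rank(pp$nonbreed_x) - rank(pp$breed_x)))
  })
  expect_lt(abs(mean(obs) - exact), 0.45)
})

test_that("larger bandwidths produce weaker connectivity", {
  breed <- range_fixture("wide", "breeding")
  nonbreed <- range_fixture("wide", "nonbreeding")
  n <- 1500
  mean_r <- vapply(c(30L, 400L, 1500L), function(b) {
    mean(vapply(1:3, function(rep) {
      pop <- build_realistic_population(
        breed, nonbreed,
        gaussian_field_params(grid_nx = 50, grid_ny = 50,
                              seed = split_seed(17L, b, rep)),
        n, rank_match_params(b, seed = split_seed(18L, b, rep)))
      global_truth_score(pop)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})
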