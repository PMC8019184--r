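test_that("pairwise distances match per-pair scalar computation", {
  D <- pairwise_distance_matrix(rbind(c(0, 0), c(3, 4)))
  expect_equal(as.vector(D), 5)

  set.seed(21)
  pts <- matrix(runif(12, -5, 5), 6, 2)
  D <- as.matrix(pairwise_distance_matrix(pts))
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(D[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  expect_error(pairwise_distance_matrix(rbind(c(0, 0), c(NA, 1))),
               "non-finite")

  # haversine: quarter circle on the default sphere (radius 6378.137 km)
  Dg <- pairwise_distance_matrix(rbind(c(0, 0), c(0, 90)),
                                 metric = "haversine")
  expect_equal(as.vector(Dg), pi / 2 * 6378137, tolerance = 1e-6)
})

test_that("Mantel statistic equals brute-force pair-loop Pearson", {
  for (seed in 1:4) {
    n <- sample(5:8, 1)
    D1 <- random_dist(n, seed)
    D2 <- random_dist(n, seed + 100)
    expect_equal(mantel_statistic(D1, D2), brute_force_mantel(D1, D2))
  }
})

test_that("Mantel statistic is affine-invariant and permutation-invariant", {
  D1 <- random_dist(7, 31)
  expect_equal(mantel_statistic(D1, 2 * as.matrix(D1)), 1)
  flipped <- 100 - as.matrix(D1); diag(flipped) <- 0
  expect_equal(mantel_statistic(D1, flipped), -1)

  # simultaneous relabelling of both matrices leaves r unchanged
  D2 <- random_dist(7, 32)
  p <- sample(7)
  expect_equal(mantel_statistic(as.matrix(D1)[p, p], as.matrix(D2)[p, p]),
               mantel_statistic(D1, D2))

  zero <- matrix(0, 4, 4)
  expect_error(mantel_statistic(zero, as.matrix(random_dist(4, 1))),
               "zero variance")
})

test_that("Mantel statistic agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  D1 <- random_dist(15, 77)
  D2 <- random_dist(15, 78)
  ref <- vegan::mantel(D1, D2, permutations = 0)
  expect_equal(mantel_statistic(D1, D2), unname(ref$statistic))
})

test_that("permutation p-value is exact for a maximal statistic", {
  D1 <- random_dist(10, 5)
  res <- mantel_permutation_test(D1, D1, n_perm = 99, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p_one_sided, 1 / 100)
})

test_that("sampled permutation p converges to the exhaustive value at n = 4", {
  D1 <- random_dist(4, 8)
  D2 <- random_dist(4, 9)
  r_obs <- mantel_statistic(D1, D2)
  m2 <- as.matrix(D2)
  lt <- lower.tri(m2)
  v1 <- as.vector(D1)
  r_all <- vapply(all_perms(4), function(p) {
    stats::cor(v1, m2[p, p][lt])
  }, numeric(1))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  res <- mantel_permutation_test(D1, D2, n_perm = 4999, seed = 10)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(res$p_one_sided - p_exact), 4 * mc_se + 1 / 5000)
})

test_that("permutation p is uniform under the null", {
  set.seed(40)
  pvals <- replicate(400, {
    res <- mantel_permutation_test(random_dist(30, sample.int(1e6, 1)),
                                   random_dist(30, sample.int(1e6, 1)),
                                   n_perm = 99,
                                   seed = sample.int(1e6, 1))
    res$p_one_sided
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.001)
  expect_lt(abs(mean(pvals) - 0.5), 4 * sqrt(1 / 12 / 400))
})

test_that("sample scores agree with direct computation and truths nest", {
  pop <- tiny_population(n = 60, seed = 13)
  ids <- sample(pop$id, 10)
  rows <- match(ids, pop$id)
  expect_equal(
    score_sample(pop, ids),
    brute_force_mantel(
      as.matrix(stats::dist(cbind(pop$breed_x[rows], pop$breed_y[rows]))),
      as.matrix(stats::dist(cbind(pop$nonbreed_x[rows], pop$nonbreed_y[rows])))
    ))

  # zone covering everything reproduces the global truth
  expect_equal(zone_truth_score(pop, rect(-1e6, -1e6, 1e6, 1e6)),
               global_truth_score(pop))
  expect_equal(score_sample(pop, pop$id), global_truth_score(pop),
               tolerance = 1e-12)
  expect_error(zone_truth_score(pop, rect(1e5, 1e5, 2e5, 2e5)),
               "need >= 3")

  # three collinear equally spaced individuals migrating rigidly: r = 1
  rigid <- rigid_population(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(score_sample(rigid, rigid$id), 1)
})

test_that("streaming global correlation equals the direct computation", {
  for (seed in c(17, 18)) {
    pop <- tiny_population(n = 301, seed = seed)
    direct <- stats::cor(
      as.vector(stats::dist(cbind(pop$breed_x, pop$breed_y))),
      as.vector(stats::dist(cbind(pop$nonbreed_x, pop$nonbreed_y))))
    expect_equal(global_truth_score(pop), direct, tolerance = 1e-12)
  }
})
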