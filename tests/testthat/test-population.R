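test_that("uniform breeding placement respects bounds and moments", {
  r <- rect(0, 0, 1, 1)
  pop <- simulate_breeding_uniform(100000, r, seed = 7)
  expect_equal(nrow(pop), 100000)
  expect_true(all(rect_contains(r, pop$breed_x, pop$breed_y)))
  se <- sqrt(1 / 12) / sqrt(100000)
  expect_lt(abs(mean(pop$breed_x) - 0.5), 4 * se)
  expect_lt(abs(mean(pop$breed_y) - 0.5), 4 * se)

  expect_equal(nrow(simulate_breeding_uniform(0, r, seed = 1)), 0)
  expect_error(rect(1, 0, 0, 1), "invalid rect")
  expect_error(simulate_breeding_uniform(10, "not a rect", seed = 1),
               "rect")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- tiny_population(seed = 9)
  b <- tiny_population(seed = 9)
  expect_identical(a, b)
  c <- tiny_population(seed = 10)
  expect_false(identical(a, c))
})

test_that("migration is a due-south shift plus lognormal displacement", {
  pop <- simulate_breeding_uniform(500, rect(0, 0, 10, 10), seed = 1)
  # degenerate displacement (meanlog = -Inf draws distance 0): pure shift
  shifted <- apply_migration(pop, migration_params(25, -Inf, 1, seed = 2))
  expect_equal(shifted$nonbreed_x, pop$breed_x)
  expect_equal(shifted$nonbreed_y, pop$breed_y - 25)

  # displacement distances: lognormal with the requested log-scale moments
  mu <- 3
  big <- simulate_breeding_uniform(1e5, rect(0, 0, 1, 1), seed = 3)
  mig <- apply_migration(big, migration_params(0, mu, 1, seed = 4))
  d <- sqrt((mig$nonbreed_x - mig$breed_x)^2 +
            (mig$nonbreed_y - mig$breed_y)^2)
  expect_true(all(d > 0))
  expect_lt(abs(stats::median(d) - exp(mu)) / exp(mu), 0.01)
  expect_lt(abs(mean(d) - exp(mu + 0.5)) / exp(mu + 0.5), 0.02)
  # log-distances are normal
  ks <- stats::ks.test(log(d[1:10000]), "pnorm", mean = mu, sd = 1)
  expect_gt(ks$p.value, 0.001)

  unset <- simulate_breeding_uniform(5, rect(0, 0, 1, 1), seed = 1)
  unset$breed_x <- NA_real_
  expect_error(apply_migration(unset, migration_params(1, 3, 1, seed = 1)),
               "breeding coordinates")
})

test_that("non-breeding restriction matches per-point containment", {
  pop <- tiny_population(n = 400, side = 100, mu = 4, seed = 5)
  regions <- list(rect(-50, -300, 40, -150), rect(60, -250, 150, -120))
  kept <- restrict_to_nonbreeding_regions(pop, regions)
  manual <- vapply(seq_len(nrow(pop)), function(i) {
    x <- pop$nonbreed_x[i]; y <- pop$nonbreed_y[i]
    any(vapply(regions, function(r) {
      x >= r$xmin && x <= r$xmax && y >= r$ymin && y <= r$ymax
    }, logical(1)))
  }, logical(1))
  expect_identical(kept$id, pop$id[manual])

  everything <- restrict_to_nonbreeding_regions(
    pop, list(rect(-1e6, -1e6, 1e6, 1e6)))
  expect_identical(everything, pop)
  nothing <- restrict_to_nonbreeding_regions(
    pop, list(rect(1e5, 1e5, 2e5, 2e5)))
  expect_equal(nrow(nothing), 0)
})

test_that("patchy simulation restricts to the non-breeding regions", {
  layout <- patchy_layout(per_patch_n = 300)
  params <- migration_params(population_defaults()$shift_south, 5, 1)
  pop <- simulate_patchy_population(layout, params, seed = 3)
  expect_lte(nrow(pop), 4 * 300)
  expect_gt(nrow(pop), 0)
  expect_true(all(rects_contain(layout$nonbreed_regions,
                                pop$nonbreed_x, pop$nonbreed_y)))
  expect_true(all(rects_contain(layout$breed_patches,
                                pop$breed_x, pop$breed_y)))

  # zero-noise limit with regions exactly at the shifted patches keeps all
  shift <- population_defaults()$shift_south
  zero_noise <- migration_params(shift, -Inf, 1)
  pop0 <- simulate_patchy_population(layout, zero_noise, seed = 4)
  expect_equal(nrow(pop0), 4 * 300)

  # overlapping patches are rejected
  expect_error(
    patchy_layout(breed_patches = rep(list(rect(0, 0, 1, 1)), 4),
                  nonbreed_regions = corner_squares(rect(0, 0, 10, 10), 2)),
    "disjoint")
})

test_that("individuals tables round-trip bit-exactly", {
  pop <- tiny_population(n = 37, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_individuals(pop, path)
  back <- read_individuals(path)
  expect_identical(back$breed_x, pop$breed_x)
  expect_identical(back$nonbreed_y, pop$nonbreed_y)
  expect_identical(back$id, pop$id)
})
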