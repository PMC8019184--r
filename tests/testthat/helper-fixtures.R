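# Small populations and matrices built in code for the unit tests.

tiny_population <- function(n = 50, side = 100, mu = 2, seed = 42) {
  pop <- simulate_breeding_uniform(n, rect(0, 0, side, side), seed = seed)
  apply_migration(pop, migration_params(2 * side, mu, 1, seed = seed + 1))
}

# rigid translation: non-breeding = breeding shifted, no noise
rigid_population <- function(breed_xy, shift = c(0, -10)) {
  new_pop <- simulate_breeding_uniform(0, rect(0, 0, 1, 1), seed = 1)
  pop <- data.frame(id = seq_len(nrow(breed_xy)),
                    breed_x = breed_xy[, 1], breed_y = breed_xy[, 2],
                    nonbreed_x = breed_xy[, 1] + shift[1],
                    nonbreed_y = breed_xy[, 2] + shift[2])
  class(pop) <- class(new_pop)
  pop
}

random_dist <- function(n, seed) {
  set.seed(seed)
  stats::dist(matrix(runif(n * 2), n, 2))
}

# Pearson correlation over unordered pairs by explicit double loop
brute_force_mantel <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  v1 <- c(); v2 <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v1 <- c(v1, m1[i, j]); v2 <- c(v2, m2[i, j])
    }
  }
  stats::cor(v1, v2)
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

square_polygon <- function(xmin, ymin, xmax, ymax,
                           season = "breeding") {
  range_polygon(list(matrix(c(xmin, ymin, xmax, ymin, xmax, ymax,
                              xmin, ymax), ncol = 2, byrow = TRUE)),
                season = season)
}
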