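#' Pairwise distance matrix for one season
#'
#' Planar coordinates use Euclidean distance (via [stats::dist()]);
#' geographic lon/lat coordinates use great-circle (haversine) distance via
#' \pkg{geosphere}. The result is the field's canonical `"dist"` container:
#' symmetric, zero diagonal, non-negative.
#'
#' @param points Two-column matrix or data frame of coordinates
#'   (x, y) or (lon, lat).
#' @param metric `"euclidean"` or `"haversine"`.
#' @return A `"dist"` object over the rows of `points`.
#' @export
pairwise_distance_matrix <- function(points, metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must have two coordinate columns")
  if (nrow(pts) < 2) stop("need at least 2 points")
  if (any(!is.finite(pts))) stop("non-finite coordinates")
  if (metric == "euclidean") {
    stats::dist(pts)
  } else {
    stats::as.dist(geosphere::distm(pts, fun = geosphere::distHaversine))
  }
}

dist_vector <- function(D) {
  if (inherits(D, "dist")) return(as.vector(D))
  m <- as.matrix(D)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  m[lower.tri(m)]
}

dist_size <- function(D) {
  if (inherits(D, "dist")) attr(D, "Size") else nrow(as.matrix(D))
}

#' Mantel correlation statistic
#'
#' Pearson correlation over the n(n-1)/2 unordered off-diagonal pairs of two
#' matched distance matrices. High values mean the relative spatial
#' arrangement of individuals is preserved between the two seasons (strong
#' migratory connectivity). A zero-variance matrix makes the statistic
#' undefined and raises an error rather than silently returning 0.
#'
#' @param D1,D2 `"dist"` objects or square symmetric matrices over the same
#'   n >= 3 individuals, in the same order.
#' @return The Mantel correlation, in \[-1, 1\].
#' @export
mantel_statistic <- function(D1, D2) {
  n1 <- dist_size(D1); n2 <- dist_size(D2)
  if (n1 != n2) stop("distance matrices must have the same size")
  if (n1 < 3) stop("Mantel statistic requires at least 3 individuals")
  v1 <- dist_vector(D1); v2 <- dist_vector(D2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("Mantel statistic undefined: zero variance in off-diagonal distances")
  }
  stats::cor(v1, v2)
}

#' Mantel permutation test
#'
#' Permutes individuals — a simultaneous identical row/column permutation of
#' the second matrix — and reports the one-sided (greater) p-value with the
#' +1 correction: `p = (count(r_perm >= r_obs) + 1) / (n_perm + 1)`.
#'
#' @param D1,D2 Matched distance matrices (`"dist"` or square matrix).
#' @param n_perm Number of permutations, >= 1 (default 999). `n_perm = 0`
#'   returns the statistic only, with `p_one_sided = NA`.
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `"mantel_result"`: list with `r`, `n`,
#'   `n_perm`, `p_one_sided`.
#' @export
mantel_permutation_test <- function(D1, D2, n_perm = 999, seed = 1L) {
  n <- dist_size(D1)
  r_obs <- mantel_statistic(D1, D2)
  if (n_perm < 1) {
    return(structure(list(r = r_obs, n = n, n_perm = 0L,
                          p_one_sided = NA_real_),
                     class = "mantel_result"))
  }
  v1 <- dist_vector(D1)
  m2 <- as.matrix(D2)
  ut <- lower.tri(m2)  # same pair ordering as dist_vector
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(v1, m2[p, p][ut])
  }, numeric(1))
  structure(list(r = r_obs, n = n, n_perm = as.integer(n_perm),
                 p_one_sided = (sum(r_perm >= r_obs) + 1) / (n_perm + 1)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f (n = %d%s)\n", x$r, x$n,
              if (x$n_perm > 0) {
                sprintf(", %d permutations, one-sided p = %.4g",
                        x$n_perm, x$p_one_sided)
              } else ""))
  invisible(x)
}

#' Serialise a Mantel result to a one-row data frame
#' @param x A `mantel_result`.
#' @return A one-row data frame with columns `r`, `n`, `n_perm`, `p_one_sided`.
#' @export
as.data.frame.mantel_result <- function(x, ...) {
  data.frame(r = x$r, n = x$n, n_perm = x$n_perm, p_one_sided = x$p_one_sided)
}

#' Mantel score of a set of sampled individuals
#'
#' The score of a simulated tracking study: Mantel correlation between the
#' breeding and non-breeding pairwise Euclidean distance matrices of exactly
#' the given individuals. Every marked individual is assumed tracked to its
#' non-breeding location with no positional uncertainty.
#'
#' @param pop A `paired_population` with both seasons set.
#' @param ids Individual ids to score (>= 3, all present in `pop`).
#' @return The Mantel correlation.
#' @export
score_sample <- function(pop, ids) {
  stopifnot(inherits(pop, "paired_population"))
  rows <- match(ids, pop$id)
  if (anyNA(rows)) stop("ids not present in population")
  if (length(rows) < 3) stop("need at least 3 individuals to score")
  pair_correlation(pop$breed_x[rows], pop$breed_y[rows],
                   pop$nonbreed_x[rows], pop$nonbreed_y[rows])
}

# streaming pairwise-distance correlation over a paired coordinate set
pair_correlation <- function(bx, by, wx, wy) {
  if (any(!is.finite(c(bx, by, wx, wy)))) stop("non-finite coordinates")
  res <- pair_distance_correlation_cpp(bx, by, wx, wy)
  if (res$degenerate) {
    stop("Mantel statistic undefined: zero variance in off-diagonal distances")
  }
  res$r
}

#' Zone-truth Mantel score
#'
#' The "true" connectivity of the strict spatial extent of sampling: the
#' Mantel score over all individuals whose breeding location lies inside the
#' zone (a rectangle or union of rectangles).
#'
#' @param pop A `paired_population`.
#' @param zone A `rect` or list of `rect`s.
#' @return The Mantel correlation over all in-zone individuals.
#' @export
zone_truth_score <- function(pop, zone) {
  if (is_rect(zone)) zone <- list(zone)
  inside <- rects_contain(zone, pop$breed_x, pop$breed_y)
  if (sum(inside) < 3) {
    stop(sprintf("only %d individuals breed inside the zone (need >= 3)",
                 sum(inside)))
  }
  score_sample(pop, pop$id[inside])
}

#' Whole-population (global-truth) Mantel score
#'
#' Mantel correlation over every individual, computed by streaming
#' accumulation over the n(n-1)/2 pairs of the two implicit pairwise
#' Euclidean distance matrices, so the default N = 10,000 population never
#' materialises its 5 x 10^7-entry matrices.
#'
#' @param pop A `paired_population` with both seasons set.
#' @return The Mantel correlation over all individuals.
#' @export
global_truth_score <- function(pop) {
  stopifnot(inherits(pop, "paired_population"))
  n <- nrow(pop)
  if (n < 3) stop("need at least 3 individuals")
  if (any(is.na(pop$nonbreed_x))) stop("non-breeding coordinates must be set")
  pair_correlation(pop$breed_x, pop$breed_y,
                   pop$nonbreed_x, pop$nonbreed_y)
}
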