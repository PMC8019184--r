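#' Distribute individuals over a range in proportion to a density surface
#'
#' The surface grid is stretched over the polygon's bounding box; cells
#' whose centre falls outside the polygon get weight zero. Each individual's
#' cell is drawn with probability proportional to cell weight, and its
#' position is uniform within the cell's intersection with the polygon
#' (uniform-in-cell proposals rejected until inside, with the cell centre —
#' known to be inside — as a deterministic fallback after 100 proposals for
#' slivers).
#'
#' @param surface A `density_surface` from [generate_gaussian_field()].
#' @param polygon A [range_polygon()].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return An n x 2 matrix of point coordinates, all inside the polygon.
#' @export
distribute_individuals <- function(surface, polygon, n, seed = 1L) {
  stopifnot(inherits(surface, "density_surface"),
            inherits(polygon, "range_polygon"), n >= 1)
  w <- surface$weights
  ny <- nrow(w); nx <- ncol(w)
  bb <- polygon_bbox(polygon)
  dx <- (bb$xmax - bb$xmin) / nx
  dy <- (bb$ymax - bb$ymin) / ny
  cx <- bb$xmin + (seq_len(nx) - 0.5) * dx
  cy <- bb$ymin + (seq_len(ny) - 0.5) * dy
  centers_x <- rep(cx, each = ny)
  centers_y <- rep(cy, times = nx)
  inside_center <- point_in_polygon(polygon, centers_x, centers_y)
  prob <- as.vector(w) * inside_center
  if (all(prob == 0)) stop("all cell weights are zero over the polygon")
  set.seed(seed)
  cells <- sample.int(nx * ny, n, replace = TRUE, prob = prob)
  x <- centers_x[cells] + (stats::runif(n) - 0.5) * dx
  y <- centers_y[cells] + (stats::runif(n) - 0.5) * dy
  bad <- !point_in_polygon(polygon, x, y)
  tries <- 0L
  while (any(bad) && tries < 100L) {
    k <- which(bad)
    x[k] <- centers_x[cells[k]] + (stats::runif(length(k)) - 0.5) * dx
    y[k] <- centers_y[cells[k]] + (stats::runif(length(k)) - 0.5) * dy
    bad[k] <- !point_in_polygon(polygon, x[k], y[k])
    tries <- tries + 1L
  }
  if (any(bad)) {
    k <- which(bad)
    x[k] <- centers_x[cells[k]]
    y[k] <- centers_y[cells[k]]
  }
  cbind(x = x, y = y)
}

#' Longitudinal-rank matching parameters
#'
#' @param bandwidth Rank half-window b, >= 0 (0 means exact-rank matching;
#'   must not exceed the population size).
#' @param seed Integer seed.
#' @return An object of class `"rank_match_params"`.
#' @export
rank_match_params <- function(bandwidth, seed = 1L) {
  if (bandwidth < 0) stop("bandwidth must be >= 0")
  structure(list(bandwidth = as.integer(bandwidth), seed = as.integer(seed)),
            class = "rank_match_params")
}

order_by_longitude <- function(pts) {
  order(pts[, 1], pts[, 2], seq_len(nrow(pts)))
}

#' Match breeding and non-breeding points by longitudinal rank
#'
#' Both point sets are ranked by longitude (x-coordinate; ties broken by
#' latitude, then input order). Breeding individuals are processed in random
#' order; each is assigned a uniformly chosen, still-unassigned non-breeding
#' point whose rank lies within `bandwidth` of its own (window clamped at
#' the range edges), giving a bijective pairing. A breeding point of rank
#' 5000 with bandwidth 1000 draws from non-breeding ranks 4000-6000. Larger
#' bandwidths scramble longitudinal order more and produce weaker migratory
#' connectivity.
#'
#' The sequential without-replacement draw almost always strands a handful
#' of late-processed individuals near the rank edges (their whole window
#' already assigned), so dead ends are repaired by augmenting-path
#' reassignment: the stranded individual displaces a neighbour within its
#' window onto another feasible slot, chaining until a free slot is
#' reached. A feasible pairing always exists (exact-rank matching satisfies
#' every window), so the repair always terminates; it touches only the few
#' edge individuals and leaves the bulk assignment untouched.
#'
#' @param breed_pts,nonbreed_pts n x 2 coordinate matrices, equal n.
#' @param params A [rank_match_params()].
#' @return A `paired_population` pairing each breeding point with its
#'   assigned non-breeding point; ids follow the breeding input order.
#' @export
match_by_longitudinal_rank <- function(breed_pts, nonbreed_pts, params) {
  stopifnot(inherits(params, "rank_match_params"))
  breed_pts <- as.matrix(breed_pts)
  nonbreed_pts <- as.matrix(nonbreed_pts)
  n <- nrow(breed_pts)
  if (nrow(nonbreed_pts) != n) {
    stop("breeding and non-breeding point sets must have equal size")
  }
  if (params$bandwidth > n) stop("bandwidth must not exceed the population size")
  b <- params$bandwidth
  breed_order <- order_by_longitude(breed_pts)    # breed_order[r] = row of rank r
  nonbreed_order <- order_by_longitude(nonbreed_pts)
  breed_rank <- integer(n); breed_rank[breed_order] <- seq_len(n)

  # Unassigned non-breeding ranks live in a Fenwick (binary indexed) tree of
  # counts, giving O(log n) window counts, k-th-remaining selection, and
  # removal. Operations are inlined so the tree vector is modified in place.
  top <- 2L^as.integer(floor(log2(n)))
  set.seed(params$seed)
  proc <- sample.int(n)  # breeding rows in random processing order
  idx <- seq_len(n)
  tree <- as.numeric(bitwAnd(idx, -idx))  # Fenwick tree of all ones
  owner <- integer(n)        # owner[slot rank] = breeding row, 0 = free
  partner_rank <- integer(n)

  take_free <- function(row) {
    # uniform draw among still-free slots in the row's window; 0 if none
    r <- breed_rank[row]
    lo <- max(1L, r - b); hi <- min(n, r + b)
    below <- 0; i <- lo - 1L
    while (i > 0L) { below <- below + tree[i]; i <- i - bitwAnd(i, -i) }
    upto <- 0; i <- hi
    while (i > 0L) { upto <- upto + tree[i]; i <- i - bitwAnd(i, -i) }
    avail <- upto - below
    if (avail < 1) return(0L)
    k <- below + sample.int(avail, 1L)
    pos <- 0L; bit <- top  # binary descent: index of the k-th remaining rank
    while (bit >= 1L) {
      np <- pos + bit
      if (np <= n && tree[np] < k) { pos <- np; k <- k - tree[np] }
      bit <- bit %/% 2L
    }
    slot <- pos + 1L
    i <- slot
    while (i <= n) { tree[i] <<- tree[i] - 1; i <- i + bitwAnd(i, -i) }
    owner[slot] <<- row
    partner_rank[row] <<- slot
    slot
  }

  visited <- logical(n)
  rotated_window <- function(row) {
    r <- breed_rank[row]
    span <- max(1L, r - b):min(n, r + b)
    start <- sample.int(length(span), 1L)  # random rotation avoids edge bias
    span[c(start:length(span), seq_len(start - 1L))]
  }
  augment <- function(row0) {
    # Kuhn-style alternating search with an explicit stack (augmenting
    # chains can be thousands of slots long): take a free slot if one
    # exists in the window, else displace an owner that can itself be
    # re-augmented. Global visited marks bound the whole search to one
    # pass over the slots it touches.
    visited[] <<- FALSE
    frames <- list(list(row = row0, span = NULL, ptr = 1L, via = 0L))
    repeat {
      d <- length(frames)
      if (d == 0L) return(FALSE)
      f <- frames[[d]]
      if (is.null(f$span)) {
        if (take_free(f$row) > 0L) {
          # success: unwind the displacement chain
          if (d > 1L) {
            for (i in d:2L) {
              s <- frames[[i]]$via
              owner[s] <<- frames[[i - 1L]]$row
              partner_rank[frames[[i - 1L]]$row] <<- s
            }
          }
          return(TRUE)
        }
        f$span <- rotated_window(f$row)
        frames[[d]] <- f
      }
      pushed <- FALSE
      while (f$ptr <= length(f$span)) {
        s <- f$span[f$ptr]
        f$ptr <- f$ptr + 1L
        if (!visited[s]) {
          visited[s] <<- TRUE
          frames[[d]] <- f
          frames[[d + 1L]] <- list(row = owner[s], span = NULL, ptr = 1L,
                                   via = s)
          pushed <- TRUE
          break
        }
      }
      if (!pushed) {
        frames[[d]] <- NULL  # dead branch: backtrack to the parent frame
      }
    }
  }

  for (row in proc) {
    if (take_free(row) == 0L) {
      if (!augment(row)) {
        stop("rank matching infeasible")  # unreachable: identity is feasible
      }
    }
  }
  nb_row <- nonbreed_order[partner_rank]
  new_paired_population(
    id = seq_len(n),
    breed_x = breed_pts[, 1], breed_y = breed_pts[, 2],
    nonbreed_x = nonbreed_pts[nb_row, 1],
    nonbreed_y = nonbreed_pts[nb_row, 2]
  )
}

#' Build a realistic spatially clustered migratory population
#'
#' Composition of the realistic-range workflow: one Gaussian random field
#' per season (seeds derived from `field_params$seed`), n individuals
#' distributed over each range in proportion to its field, and seasons
#' linked by longitudinal-rank matching.
#'
#' @param breed_range,nonbreed_range [range_polygon()]s.
#' @param field_params A [gaussian_field_params()].
#' @param n Individuals per season.
#' @param rank_params A [rank_match_params()].
#' @return A `paired_population`.
#' @export
build_realistic_population <- function(breed_range, nonbreed_range,
                                       field_params, n, rank_params) {
  fp_b <- field_params; fp_b$seed <- split_seed(field_params$seed, 1L)
  fp_n <- field_params; fp_n$seed <- split_seed(field_params$seed, 2L)
  surf_b <- generate_gaussian_field(fp_b)
  surf_n <- generate_gaussian_field(fp_n)
  breed_pts <- distribute_individuals(surf_b, breed_range, n,
                                      seed = split_seed(field_params$seed, 3L))
  nonbreed_pts <- distribute_individuals(surf_n, nonbreed_range, n,
                                         seed = split_seed(field_params$seed, 4L))
  match_by_longitudinal_rank(breed_pts, nonbreed_pts, rank_params)
}
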