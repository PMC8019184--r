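#' Range polygon for one season
#'
#' A lightweight container for a (multi)polygon range: a list of rings, each
#' an m x 2 matrix of vertices. Containment is decided by even-odd ray
#' casting over all rings, so interior rings act as holes. No simple-feature
#' library is required; the reader handles the GeoJSON Polygon/MultiPolygon
#' subset the bundled fixtures use.
#'
#' @param rings List of m x 2 numeric matrices (vertex coordinates; closing
#'   vertex optional).
#' @param season `"breeding"` or `"nonbreeding"`.
#' @param crs `"planar"` (Euclidean map units) or `"geographic"` (lon/lat).
#' @return An object of class `"range_polygon"`.
#' @export
range_polygon <- function(rings, season = c("breeding", "nonbreeding"),
                          crs = c("planar", "geographic")) {
  season <- match.arg(season)
  crs <- match.arg(crs)
  stopifnot(is.list(rings), length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) {
      stop("each ring needs >= 3 vertices with 2 coordinates")
    }
    # drop an explicit closing vertex; ray casting closes rings implicitly
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) stop("degenerate ring")
    r
  })
  total_area <- sum(vapply(rings, ring_area, numeric(1)))
  if (total_area <= 0) stop("polygon has zero area")
  structure(list(rings = rings, season = season, crs = crs),
            class = "range_polygon")
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(nrow(ring), seq_len(nrow(ring) - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @export
print.range_polygon <- function(x, ...) {
  bb <- polygon_bbox(x)
  cat(sprintf("<range_polygon: %s, %d ring(s), %s, bbox [%g, %g] x [%g, %g]>\n",
              x$season, length(x$rings), x$crs,
              bb$xmin, bb$xmax, bb$ymin, bb$ymax))
  invisible(x)
}

#' Bounding rectangle of a range polygon
#' @param polygon A `range_polygon`.
#' @return A [rect()].
#' @export
polygon_bbox <- function(polygon) {
  xs <- unlist(lapply(polygon$rings, function(r) r[, 1]))
  ys <- unlist(lapply(polygon$rings, function(r) r[, 2]))
  rect(min(xs), min(ys), max(xs), max(ys))
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorised over points, looping only over polygon edges. Points exactly
#' on an edge are a measure-zero event under the continuous samplers and are
#' resolved by the parity rule.
#'
#' @param polygon A `range_polygon`.
#' @param x,y Numeric coordinate vectors.
#' @return Logical vector.
#' @export
point_in_polygon <- function(polygon, x, y) {
  inside <- rep(FALSE, length(x))
  for (ring in polygon$rings) {
    rx <- ring[, 1]; ry <- ring[, 2]
    m <- length(rx)
    j <- m
    for (i in seq_len(m)) {
      crosses <- ((ry[i] > y) != (ry[j] > y)) &
        (x < (rx[j] - rx[i]) * (y - ry[i]) / (ry[j] - ry[i]) + rx[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

#' Read a range polygon from GeoJSON
#'
#' Accepts a Polygon or MultiPolygon geometry, bare or wrapped in a Feature
#' or single-feature FeatureCollection.
#'
#' @param path Path to a GeoJSON file.
#' @param season Season label for the range.
#' @param crs Coordinate interpretation; see [range_polygon()].
#' @return A `range_polygon`.
#' @export
read_range_polygon <- function(path, season = c("breeding", "nonbreeding"),
                               crs = c("planar", "geographic")) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(g$type, "FeatureCollection")) {
    if (length(g$features) != 1) stop("expected a single-feature GeoJSON")
    g <- g$features[[1]]
  }
  if (identical(g$type, "Feature")) g <- g$geometry
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  rings <- switch(
    g$type,
    Polygon = lapply(g$coordinates, ring_mat),
    MultiPolygon = unlist(lapply(g$coordinates,
                                 function(poly) lapply(poly, ring_mat)),
                          recursive = FALSE),
    stop("unsupported GeoJSON geometry type: ", g$type)
  )
  range_polygon(rings, season = season, crs = crs)
}

#' Bundled synthetic range fixtures
#'
#' Three synthetic species-range pairs (breeding + non-breeding GeoJSON
#' polygons) shipped with the package: `"wide"` (a broad blocky range),
#' `"compact"` (a small contained range) and `"elongated"` (a long thin
#' range). They are synthetic stand-ins with geometries comparable to real
#' published range maps, not replications of any species' range.
#'
#' @param shape `"wide"`, `"compact"` or `"elongated"`.
#' @param season `"breeding"` or `"nonbreeding"`.
#' @return A `range_polygon` (planar coordinates).
#' @export
range_fixture <- function(shape = c("wide", "compact", "elongated"),
                          season = c("breeding", "nonbreeding")) {
  shape <- match.arg(shape)
  season <- match.arg(season)
  path <- system.file("extdata",
                      sprintf("synthetic_range_%s_%s.geojson", shape, season),
                      package = "mantelmc", mustWork = TRUE)
  read_range_polygon(path, season = season, crs = "planar")
}
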