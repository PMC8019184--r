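#' Axis-aligned rectangle in planar map units
#'
#' Rectangles describe both range supports (the bounded uniform breeding
#' range) and every rectangular sampling footprint. Containment uses closed
#' intervals: a point exactly on the boundary counts as inside.
#'
#' @param xmin,ymin,xmax,ymax Numeric bounds; `xmax > xmin`, `ymax > ymin`.
#' @return An object of class `"rect"`.
#' @export
rect <- function(xmin, ymin, xmax, ymax) {
  vals <- c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  if (any(!is.finite(vals))) {
    stop("rect bounds must be finite numbers")
  }
  if (xmax <= xmin || ymax <= ymin) {
    stop(sprintf(
      "invalid rect: need xmax > xmin and ymax > ymin (got [%g, %g] x [%g, %g])",
      xmin, xmax, ymin, ymax
    ))
  }
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "rect")
}

#' @export
print.rect <- function(x, ...) {
  cat(sprintf("<rect [%g, %g] x [%g, %g]>\n", x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

is_rect <- function(x) inherits(x, "rect")

#' Rectangle area
#' @param r A `rect`.
#' @return Numeric area in squared map units.
#' @export
rect_area <- function(r) (r$xmax - r$xmin) * (r$ymax - r$ymin)

#' Rectangle centroid
#' @param r A `rect`.
#' @return Length-2 numeric vector `(x, y)`.
#' @export
rect_centroid <- function(r) c((r$xmin + r$xmax) / 2, (r$ymin + r$ymax) / 2)

#' Point-in-rectangle test (closed boundaries)
#' @param r A `rect`.
#' @param x,y Numeric vectors of coordinates.
#' @return Logical vector.
#' @export
rect_contains <- function(r, x, y) {
  x >= r$xmin & x <= r$xmax & y >= r$ymin & y <= r$ymax
}

#' Membership in a union of rectangles
#' @param rects A list of `rect` objects.
#' @param x,y Numeric vectors of coordinates.
#' @return Logical vector: inside at least one rectangle.
#' @export
rects_contain <- function(rects, x, y) {
  stopifnot(length(rects) >= 1)
  inside <- rep(FALSE, length(x))
  for (r in rects) inside <- inside | rect_contains(r, x, y)
  inside
}

#' Axis-aligned bounding rectangle of a set of rectangles
#' @param rects A list of `rect` objects.
#' @return A single `rect` covering all of them.
#' @export
rect_bbox <- function(rects) {
  stopifnot(length(rects) >= 1)
  rect(
    min(vapply(rects, function(r) r$xmin, numeric(1))),
    min(vapply(rects, function(r) r$ymin, numeric(1))),
    max(vapply(rects, function(r) r$xmax, numeric(1))),
    max(vapply(rects, function(r) r$ymax, numeric(1)))
  )
}

#' Centred square helper
#'
#' @param center Length-2 numeric `(x, y)`.
#' @param side Side length, > 0.
#' @return A `rect`.
#' @export
centred_square <- function(center, side) {
  stopifnot(side > 0)
  rect(center[1] - side / 2, center[2] - side / 2,
       center[1] + side / 2, center[2] + side / 2)
}

rects_overlap <- function(a, b) {
  a$xmin < b$xmax && b$xmin < a$xmax && a$ymin < b$ymax && b$ymin < a$ymax
}

rects_pairwise_disjoint <- function(rects) {
  n <- length(rects)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (rects_overlap(rects[[i]], rects[[j]])) return(FALSE)
    }
  }
  TRUE
}
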