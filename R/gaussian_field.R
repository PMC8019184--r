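#' Gaussian random field parameters
#'
#' The realistic populations are spatially clustered by drawing an
#' occurrence-probability surface from a stationary Gaussian random field
#' with squared-exponential covariance. `autocorr_range` is measured in grid
#' cells; `magnitude` is the variance of the latent field. After simulation
#' the field is min-max scaled to \[0, 1\], so the magnitude mainly matters
#' relative to any later additive structure; the study defaults are a range
#' of 10 cells and a magnitude of 100.
#'
#' @param grid_nx,grid_ny Grid cell counts (both >= 2).
#' @param autocorr_range Correlation range in cells, > 0.
#' @param magnitude Latent-field variance, > 0.
#' @param seed Integer seed.
#' @return An object of class `"gaussian_field_params"`.
#' @export
gaussian_field_params <- function(grid_nx = 100L, grid_ny = 100L,
                                  autocorr_range = 10, magnitude = 100,
                                  seed = 1L) {
  if (grid_nx < 2 || grid_ny < 2) {
    stop("degenerate grid: need at least 2 cells in each direction")
  }
  if (autocorr_range <= 0) stop("autocorr_range must be > 0")
  # magnitude 0 is the degenerate constant-field limit (weights all 0.5)
  if (magnitude < 0) stop("magnitude must be >= 0")
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 autocorr_range = autocorr_range, magnitude = magnitude,
                 seed = as.integer(seed)),
            class = "gaussian_field_params")
}

#' Simulate a scaled Gaussian random field density surface
#'
#' Simulates a stationary zero-mean Gaussian field with squared-exponential
#' covariance `magnitude * exp(-(h / range)^2)` on the grid by circulant
#' embedding: the covariance is wrapped onto a doubled torus, its FFT gives
#' the embedding eigenvalues (small negative values from the approximate
#' embedding are clamped to zero), and one complex-noise FFT yields the
#' field. The result is min-max scaled to \[0, 1\]; a constant field (zero
#' sample range) maps to 0.5 everywhere, which is equivalent for
#' proportional sampling.
#'
#' @param params A [gaussian_field_params()].
#' @return An object of class `"density_surface"`: list with `weights`
#'   (`grid_ny` x `grid_nx` matrix in \[0, 1\], rows indexing y from the
#'   bottom), and unit cell geometry (`origin`, `cell_dx`, `cell_dy`) that
#'   [distribute_individuals()] re-anchors onto a polygon's bounding box.
#' @export
generate_gaussian_field <- function(params) {
  stopifnot(inherits(params, "gaussian_field_params"))
  nx <- params$grid_nx; ny <- params$grid_ny
  mx <- 2L * nx; my <- 2L * ny
  # torus distances on the embedding grid, in cells
  hx <- pmin(0:(mx - 1), mx - 0:(mx - 1))
  hy <- pmin(0:(my - 1), my - 0:(my - 1))
  h2 <- outer(hy^2, hx^2, "+")
  C <- params$magnitude * exp(-h2 / params$autocorr_range^2)
  lambda <- Re(stats::fft(C))
  lambda[lambda < 0] <- 0
  set.seed(params$seed)
  Z <- matrix(stats::rnorm(mx * my), my, mx) +
    1i * matrix(stats::rnorm(mx * my), my, mx)
  F <- stats::fft(sqrt(lambda) * Z) / sqrt(mx * my)
  field <- Re(F)[seq_len(ny), seq_len(nx), drop = FALSE]
  rng <- range(field)
  weights <- if (rng[2] > rng[1]) {
    (field - rng[1]) / (rng[2] - rng[1])
  } else {
    matrix(0.5, ny, nx)
  }
  structure(list(weights = weights, origin = c(0, 0),
                 cell_dx = 1, cell_dy = 1, params = params),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface: %d x %d cells, weights in [%g, %g]>\n",
              ncol(x$weights), nrow(x$weights),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Empirical lag correlation of a density surface
#'
#' Correlation between cell weights and weights offset by `lag` cells,
#' pooled over the x and y directions — a cheap correlogram used to verify
#' that simulated fields are positively autocorrelated at short lags.
#'
#' @param surface A `density_surface`.
#' @param lag Offset in cells.
#' @return Pearson correlation at that lag.
#' @export
surface_lag_correlation <- function(surface, lag) {
  w <- surface$weights
  stopifnot(lag >= 1, lag < ncol(w), lag < nrow(w))
  a <- c(w[, seq_len(ncol(w) - lag)], w[seq_len(nrow(w) - lag), ])
  b <- c(w[, (lag + 1):ncol(w)], w[(lag + 1):nrow(w), ])
  stats::cor(a, b)
}

#' Export a density surface as an ESRI ASCII grid
#'
#' Plain-text raster for inspection in GIS tools; rows are written from the
#' top (north) as the dialect requires.
#'
#' @param surface A `density_surface`.
#' @param path Output file path.
#' @param origin Lower-left corner `(x, y)` of the grid.
#' @param cell_size Cell size in map units (square cells in this dialect).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path, origin = surface$origin,
                             cell_size = surface$cell_dx) {
  w <- surface$weights
  header <- c(
    sprintf("ncols %d", ncol(w)),
    sprintf("nrows %d", nrow(w)),
    sprintf("xllcorner %g", origin[1]),
    sprintf("yllcorner %g", origin[2]),
    sprintf("cellsize %g", cell_size),
    "NODATA_value -9999"
  )
  rows <- apply(w[rev(seq_len(nrow(w))), , drop = FALSE], 1,
                function(r) paste(sprintf("%.6g", r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}
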