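#' Construct a regular 2D lattice at the isocenter-depth plane
#'
#' Grids are axis-aligned, uniformly spaced, with identical spacing in x
#' (cross-plane, leaf-travel direction) and y (in-plane, jaw direction).
#' Coordinates are cm projected to the isocenter plane; the lattice always
#' contains the central-axis point (0, 0) when the limits straddle it.
#'
#' @param xlim,ylim length-2 numeric limits in cm.
#' @param spacing lattice spacing in cm (default 0.1, i.e. 1 mm).
#' @return a list with components `x`, `y` (ascending coordinate vectors)
#'   and `spacing`.
#' @export
make_grid <- function(xlim, ylim = xlim, spacing = 0.1) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, spacing > 0,
            xlim[1] < xlim[2], ylim[1] < ylim[2])
  ax <- function(lim) spacing * seq(ceiling(lim[1] / spacing - 1e-9),
                                    floor(lim[2] / spacing + 1e-9))
  list(x = ax(xlim), y = ax(ylim), spacing = spacing)
}

## shared scaffolding for fluence_grid / dose_grid: values is an nx-by-ny
## matrix, rows indexing x and columns indexing y
new_plane <- function(values, grid, class, normalization = "absolute") {
  stopifnot(is.matrix(values),
            nrow(values) == length(grid$x), ncol(values) == length(grid$y))
  structure(list(values = values, x = grid$x, y = grid$y,
                 spacing = grid$spacing, normalization = normalization),
            class = c(class, "dose_plane"))
}

#' Planar fluence container
#'
#' @param values nx-by-ny matrix of relative energy fluence (rows index x).
#' @param grid lattice from [make_grid()].
#' @return object of class `fluence_grid`.
#' @export
fluence_grid <- function(values, grid) {
  if (any(values < 0)) stop("fluence values must be non-negative")
  new_plane(values, grid, "fluence_grid")
}

#' Planar dose container
#'
#' @param values nx-by-ny matrix of dose (relative, or cGy when an external
#'   calibration scalar has been applied); rows index x.
#' @param grid lattice from [make_grid()].
#' @param normalization character tag recorded in metadata
#'   (`"absolute"`, `"max"` or `"point"`).
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(values, grid, normalization = "absolute") {
  new_plane(values, grid, "dose_grid", normalization)
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<%s> %d x %d points, spacing %.3g cm, x [%g, %g], y [%g, %g]\n",
              class(x)[1], length(x$x), length(x$y), x$spacing,
              min(x$x), max(x$x), min(x$y), max(x$y)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], normalization: %s\n",
              rng[1], rng[2], x$normalization))
  invisible(x)
}

grid_of <- function(plane) list(x = plane$x, y = plane$y, spacing = plane$spacing)

## bilinear interpolation of a plane at arbitrary query points;
## NA outside the grid extent
interp_bilinear <- function(plane, xq, yq) {
  x <- plane$x; y <- plane$y; V <- plane$values
  nx <- length(x); ny <- length(y)
  out <- rep(NA_real_, length(xq))
  ok <- xq >= x[1] & xq <= x[nx] & yq >= y[1] & yq <= y[ny] &
    is.finite(xq) & is.finite(yq)
  if (!any(ok)) return(out)
  xi <- pmin(pmax(findInterval(xq[ok], x), 1L), nx - 1L)
  yi <- pmin(pmax(findInterval(yq[ok], y), 1L), ny - 1L)
  h <- plane$spacing
  tx <- (xq[ok] - x[xi]) / h
  ty <- (yq[ok] - y[yi]) / h
  out[ok] <- V[cbind(xi, yi)] * (1 - tx) * (1 - ty) +
    V[cbind(xi + 1L, yi)] * tx * (1 - ty) +
    V[cbind(xi, yi + 1L)] * (1 - tx) * ty +
    V[cbind(xi + 1L, yi + 1L)] * tx * ty
  out
}
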