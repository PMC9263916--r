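#' Bivariate polynomial surface
#'
#' An elevation surface of the form
#' \deqn{z = \sum_{k=0}^{n} \sum_{i=0}^{k} a_{ki}\, X^{k-i} Y^{i}}
#' where `X = (x - center_x) / scale_x` and `Y = (y - center_y) / scale_y`
#' are conditioned coordinates. Conditioning (centering and scaling the
#' planar coordinates to about `[-1, 1]`) is essential: raw monomials of
#' field-scale coordinates make the degree-3/4 normal equations
#' numerically singular. A degree-`n` surface has `(n+1)(n+2)/2`
#' coefficients, stored in `(k, i)` lexicographic order and named
#' `a<k><i>`.
#'
#' @param degree polynomial degree `n >= 0`.
#' @param coefficients numeric vector of length `(n+1)(n+2)/2`.
#' @param center,scale conditioning `c(x, y)` center and scale.
#' @return object of class `poly_surface`.
#' @export
poly_surface <- function(degree, coefficients, center = c(0, 0),
                         scale = c(1, 1)) {
  degree <- as.integer(degree)
  if (degree < 0) stop("degree must be >= 0")
  n_coef <- (degree + 1) * (degree + 2) / 2
  if (length(coefficients) != n_coef)
    stop(sprintf("degree %d needs %d coefficients, got %d",
                 degree, n_coef, length(coefficients)))
  if (any(scale <= 0)) stop("conditioning scale must be positive")
  names(coefficients) <- surface_term_names(degree)
  structure(list(
    degree = degree,
    coefficients = coefficients,
    center = as.numeric(center),
    scale = as.numeric(scale)
  ), class = "poly_surface")
}

surface_term_names <- function(degree) {
  unlist(lapply(0:degree, function(k) sprintf("a%d%d", k, 0:k)))
}

# design matrix of conditioned monomials X^(k-i) Y^i, (k, i) lexicographic
poly_basis <- function(X, Y, degree) {
  cols <- vector("list", (degree + 1) * (degree + 2) / 2)
  j <- 0
  for (k in 0:degree) for (i in 0:k) {
    j <- j + 1
    cols[[j]] <- X^(k - i) * Y^i
  }
  out <- do.call(cbind, cols)
  colnames(out) <- surface_term_names(degree)
  out
}

#' Evaluate a polynomial surface
#'
#' @param surface a [poly_surface()].
#' @param x,y coordinates (m); vectors of equal length.
#' @return elevations (m).
#' @export
evaluate_surface <- function(surface, x, y) {
  stopifnot(inherits(surface, "poly_surface"))
  X <- (x - surface$center[1]) / surface$scale[1]
  Y <- (y - surface$center[2]) / surface$scale[2]
  drop(poly_basis(X, Y, surface$degree) %*% surface$coefficients)
}

#' Fit a polynomial surface to scattered elevations by least squares
#'
#' Solves the linear least-squares problem for the surface coefficients
#' on conditioned coordinates via a QR decomposition. The fit fails
#' loudly when the design matrix is rank deficient (for example, degree 4
#' on points lying exactly on the four lines of a rectangular ring, where
#' the quartic `(x - x1)(x - x2)(y - y1)(y - y2)` vanishes at every
#' point) rather than returning an arbitrary minimum-norm solution.
#'
#' @param points data frame with columns `x`, `y`, `z` (m).
#' @param degree polynomial degree.
#' @param rank_tol relative tolerance for the rank check.
#' @return a [poly_surface()] with attributes `rss` (residual sum of
#'   squares) and `n_points`.
#' @export
fit_polynomial_dtm <- function(points, degree, rank_tol = 1e-10) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  degree <- as.integer(degree)
  n_coef <- (degree + 1) * (degree + 2) / 2
  if (nrow(points) < n_coef)
    stop(sprintf("need at least %d points for a degree-%d surface, got %d",
                 n_coef, degree, nrow(points)))
  cx <- mean(range(points$x)); cy <- mean(range(points$y))
  sx <- diff(range(points$x)) / 2; sy <- diff(range(points$y)) / 2
  if (degree >= 1 && (sx <= 0 || sy <= 0))
    stop("degenerate point geometry: zero extent in x or y")
  if (degree == 0) { sx <- 1; sy <- 1 }
  A <- poly_basis((points$x - cx) / sx, (points$y - cy) / sy, degree)
  qrA <- qr(A, tol = rank_tol)
  if (qrA$rank < n_coef)
    stop(sprintf(
      "rank-deficient design (rank %d < %d): degree-%d surface is not identifiable from these points",
      qrA$rank, n_coef, degree))
  coef <- qr.coef(qrA, points$z)
  surf <- poly_surface(degree, unname(coef), center = c(cx, cy),
                       scale = c(sx, sy))
  attr(surf, "rss") <- sum((points$z - drop(A %*% coef))^2)
  attr(surf, "n_points") <- nrow(points)
  surf
}

#' Rasterize a polynomial surface on the grid of an existing raster
#'
#' @param surface a [poly_surface()].
#' @param like a [raster_grid()] providing the grid geometry.
#' @return a [raster_grid()] of surface elevations.
#' @export
surface_raster <- function(surface, like) {
  stopifnot(inherits(like, "raster_grid"))
  xc <- pixel_centers_x(like)
  yc <- pixel_centers_y(like)
  X <- (xc - surface$center[1]) / surface$scale[1]
  Y <- (yc - surface$center[2]) / surface$scale[2]
  v <- matrix(0, nrow = length(yc), ncol = length(xc))
  j <- 0
  for (k in 0:surface$degree) for (i in 0:k) {
    j <- j + 1
    v <- v + surface$coefficients[j] * outer(Y^i, X^(k - i))
  }
  raster_grid(v, origin = like$origin, pixel_size = like$pixel_size,
              nodata = like$nodata)
}

#' Serialize / restore a fitted surface as YAML
#'
#' Stores degree, conditioning and the coefficient list in `(k, i)`
#' lexicographic order.
#'
#' @param surface a [poly_surface()].
#' @param path file path.
#' @return `write_surface_yaml` returns `path` invisibly;
#'   `read_surface_yaml` returns a [poly_surface()].
#' @export
write_surface_yaml <- function(surface, path) {
  stopifnot(inherits(surface, "poly_surface"))
  yaml::write_yaml(list(
    degree = surface$degree,
    center = as.list(surface$center),
    scale = as.list(surface$scale),
    coefficients = as.list(unname(surface$coefficients))
  ), path, precision = 12)
  invisible(path)
}

#' @rdname write_surface_yaml
#' @export
read_surface_yaml <- function(path) {
  s <- yaml::read_yaml(path)
  poly_surface(s$degree, unlist(s$coefficients),
               center = unlist(s$center), scale = unlist(s$scale))
}
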