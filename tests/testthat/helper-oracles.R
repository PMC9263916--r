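# Independent oracles used across the suite. Each reimplements the
# checked quantity from first principles, never by calling the package
# path it verifies.

# least squares for z = sum a_ki X^(k-i) Y^i via explicit normal equations
oracle_poly_fit <- function(points, degree, center, scale) {
  X <- (points$x - center[1]) / scale[1]
  Y <- (points$y - center[2]) / scale[2]
  cols <- list()
  for (k in 0:degree) for (i in 0:k)
    cols[[length(cols) + 1]] <- X^(k - i) * Y^i
  A <- do.call(cbind, cols)
  solve(t(A) %*% A, t(A) %*% points$z)[, 1]
}

# direct monomial summation of the conditioned polynomial
oracle_poly_eval <- function(coef, degree, center, scale, x, y) {
  X <- (x - center[1]) / scale[1]
  Y <- (y - center[2]) / scale[2]
  z <- 0; j <- 0
  for (k in 0:degree) for (i in 0:k) {
    j <- j + 1
    z <- z + coef[j] * X^(k - i) * Y^i
  }
  z
}

# sort + linear interpolation percentile at position q/100 * (N - 1)
oracle_percentile <- function(values, q) {
  v <- sort(values)
  pos <- q / 100 * (length(v) - 1)
  lo <- floor(pos); hi <- ceiling(pos)
  v[lo + 1] + (pos - lo) * (v[hi + 1] - v[lo + 1])
}

# brute-force perimeter tiling count: corner squares diagonally off the
# four corners plus ceil(L / unit) pieces along each full side
oracle_ring_count <- function(region, unit = 1, depth = 0.5) {
  4 + 2 * ceiling(region[1] / unit) + 2 * ceiling(region[2] / unit)
}

# closed-form OLS slope/intercept
oracle_ols <- function(x, y) {
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(a = a, b = mean(y) - a * mean(x))
}

# covariance-formula Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# brute-force enumeration of ordered distinct flight pairs x held groups
oracle_cv_count <- function(n_reps, n_groups) {
  n <- 0
  for (tr in seq_len(n_reps)) for (va in seq_len(n_reps))
    if (tr != va) n <- n + n_groups
  n
}

# constant raster helper
const_raster <- function(value, n = 10, pixel_size = 1, origin = c(0, 0)) {
  raster_grid(matrix(value, n, n), origin = origin, pixel_size = pixel_size)
}
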