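test_that("polynomial surface fitting matches a normal-equations oracle", {
  set.seed(17)
  # degree 0: the least-squares constant is the mean
  pts <- data.frame(x = runif(20), y = runif(20), z = rnorm(20))
  s0 <- fit_polynomial_dtm(pts, 0)
  expect_equal(unname(s0$coefficients), mean(pts$z))

  # degree 1 through three non-collinear points: exact interpolation
  tri <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1), z = c(1, 3, 2))
  s1 <- fit_polynomial_dtm(tri, 1)
  expect_equal(evaluate_surface(s1, tri$x, tri$y), tri$z, tolerance = 1e-10)
  expect_lt(attr(s1, "rss"), 1e-18)

  # random small instances against the independent solver
  for (degree in 1:4) {
    n <- 60 + degree * 40
    pts <- data.frame(x = runif(n, 0, 30), y = runif(n, 0, 20))
    pts$z <- 100 + 0.1 * pts$x - 0.05 * pts$y + 0.01 * pts$x * pts$y / 10 +
      rnorm(n, 0, 0.05)
    fit <- fit_polynomial_dtm(pts, degree)
    oc <- oracle_poly_fit(pts, degree, fit$center, fit$scale)
    expect_equal(unname(fit$coefficients), unname(oc), tolerance = 1e-8)
  }
})

test_that("a generating polynomial is recovered exactly", {
  g <- expand.grid(x = seq(0, 19), y = seq(0, 19))
  g$z <- 2 + 0.1 * g$x - 0.05 * g$y + 0.01 * g$x * g$y
  fit <- fit_polynomial_dtm(g, 2)
  expect_lt(max(abs(evaluate_surface(fit, g$x, g$y) - g$z)), 1e-8)
})

test_that("surface evaluation equals direct monomial summation", {
  set.seed(23)
  for (degree in 0:4) {
    n_coef <- (degree + 1) * (degree + 2) / 2
    surf <- poly_surface(degree, rnorm(n_coef), center = c(3, -2),
                         scale = c(7, 5))
    x <- runif(50, -10, 10); y <- runif(50, -10, 10)
    expect_equal(evaluate_surface(surf, x, y),
                 oracle_poly_eval(surf$coefficients, degree, surf$center,
                                  surf$scale, x, y),
                 tolerance = 1e-12)
  }
  s <- poly_surface(0, 5)
  expect_equal(evaluate_surface(s, c(-4, 0, 9), c(1, 1, 1)), rep(5, 3))
  plane <- poly_surface(1, c(0, 1, 1))
  expect_equal(evaluate_surface(plane, 1, 2), 3)
})

test_that("rank-deficient designs fail loudly", {
  # too few points
  expect_error(fit_polynomial_dtm(
    data.frame(x = 1:3, y = 1:3, z = 1:3), 2), "at least")
  # collinear points cannot identify a plane
  col <- data.frame(x = 1:10, y = 2 * (1:10), z = rnorm(10))
  expect_error(fit_polynomial_dtm(col, 1), "rank-deficient")
  # exactly tiled ring: degree 4 vanishes on the four centroid lines
  ring <- build_outer_rois(c(8, 6))
  pts <- data.frame(x = (ring$xmin + ring$xmax) / 2,
                    y = (ring$ymin + ring$ymax) / 2)
  pts$z <- rnorm(nrow(pts))
  expect_error(fit_polynomial_dtm(pts, 4), "rank-deficient")
  # a jittered (hand-placed) ring makes degree 4 identifiable
  ringj <- build_outer_rois(c(8, 6), jitter_sd = 0.02, seed = 3)
  ptsj <- data.frame(x = (ringj$xmin + ringj$xmax) / 2,
                     y = (ringj$ymin + ringj$ymax) / 2)
  ptsj$z <- rnorm(nrow(ptsj))
  expect_s3_class(fit_polynomial_dtm(ptsj, 4), "poly_surface")
})

test_that("off-season differencing subtracts aligned rasters", {
  r <- const_raster(100, n = 8)
  expect_true(all(method_m1(r, r)$values == 0))
  r2 <- const_raster(101.5, n = 8)
  expect_true(all(method_m1(r2, r)$values == 1.5))
  misaligned <- const_raster(100, n = 8, origin = c(1, 0))
  expect_error(method_m1(r, misaligned), "not aligned")

  # nodata propagates
  v <- matrix(100, 8, 8); v[2, 2] <- -9999
  rn <- raster_grid(v, pixel_size = 1)
  out <- method_m1(rn, r)
  expect_equal(out$values[2, 2], -9999)
  expect_true(all(out$values[-10] == 0))
})

test_that("off-season differencing inherits the datum gap between flights", {
  lay <- field_layout(2, plot_cols = 2)
  ter <- terrain_spec(default_terrain(lay$region))
  can <- canopy_vegetative()
  h <- generate_true_heights(lay, can, 21)
  on <- render_dsm(lay, ter, can,
                   flight_scenario(-90, FALSE, FALSE, "on_season", 1, 61),
                   noise_none(), 0.05, h, datum_offset = 0)
  off <- render_dsm(lay, ter, NULL,
                    flight_scenario(-90, FALSE, FALSE, "pre_germination", 1, 61),
                    noise_none(), 0.05, datum_offset = 0.8)
  off0 <- render_dsm(lay, ter, NULL,
                     flight_scenario(-90, FALSE, FALSE, "pre_germination", 1, 61),
                     noise_none(), 0.05, datum_offset = 0)
  chm <- method_m1(on, off)
  chm0 <- method_m1(on, off0)
  expect_equal(max(abs(chm0$values - chm$values - 0.8)), 0, tolerance = 1e-9)
})

test_that("percentile differencing reads cluster separation", {
  # constant ROI: no height
  r <- const_raster(10, n = 10)
  expect_equal(method_m2(r, list(xmin = 0, xmax = 10, ymin = 0, ymax = 10)), 0)
  # 100 soil pixels at 10, 100 canopy pixels at 12: both percentiles
  # land inside their cluster
  v <- matrix(c(rep(10, 100), rep(12, 100)), 10, 20)
  r2 <- raster_grid(v, pixel_size = 1)
  expect_equal(method_m2(r2, list(xmin = 0, xmax = 20, ymin = 0, ymax = 10)), 2)
  # soil hidden: the lower percentile climbs into the canopy
  v3 <- matrix(12, 10, 20); v3[1, 1] <- 10   # a single soil pixel (0.5%)
  r3 <- raster_grid(v3, pixel_size = 1)
  collapsed <- method_m2(r3, list(xmin = 0, xmax = 20, ymin = 0, ymax = 10))
  expect_lt(collapsed, 0.5)
})

test_that("the polynomial-terrain method recovers canopy on clean terrain", {
  # DSM = polynomial terrain + canopy confined to inner rectangles; the
  # ring sees pure terrain. On planar terrain the ROI median equals the
  # surface at the centroid (symmetric pixel set), so recovery is exact
  # for any fit degree >= 1. Curved terrain adds a small median
  # aggregation bias (the median of a quadratic over a rectangle is not
  # its centroid value), bounding recovery at millimeter level.
  region <- c(8, 6)
  ring <- build_outer_rois(region)
  nx <- 200; ny <- 160
  r0 <- raster_grid(matrix(0, ny, nx), origin = c(-1, -1), pixel_size = 0.05)
  canopy <- matrix(0, ny, nx)
  canopy[60:80, 60:100] <- 0.9   # a canopy patch well inside the region

  plane <- poly_surface(1, c(50, 0.4, -0.3), center = region / 2,
                        scale = region / 2)
  dsm_p <- raster_grid(surface_raster(plane, r0)$values + canopy,
                       origin = c(-1, -1), pixel_size = 0.05)
  for (degree in 1:3)
    expect_lt(max(abs(method_m3(dsm_p, ring, degree)$values - canopy)), 1e-6)

  quad <- poly_surface(2, c(50, 0.4, -0.3, 0.1, 0.05, -0.08),
                       center = region / 2, scale = region / 2)
  dsm_q <- raster_grid(surface_raster(quad, r0)$values + canopy,
                       origin = c(-1, -1), pixel_size = 0.05)
  for (degree in 2:3)
    expect_lt(max(abs(method_m3(dsm_q, ring, degree)$values - canopy)), 2e-3)
})

test_that("percentile and polynomial methods are datum invariant", {
  lay <- field_layout(2, plot_cols = 2)
  ter <- terrain_spec(default_terrain(lay$region))
  can <- canopy_vegetative()
  h <- generate_true_heights(lay, can, 21)
  fl <- flight_scenario(-90, FALSE, FALSE, "on_season", 1, 62)
  d0 <- render_dsm(lay, ter, can, fl, noise_none(), 0.05, h, datum_offset = 0)
  d1 <- render_dsm(lay, ter, can, fl, noise_none(), 0.05, h,
                   datum_offset = 2.3)
  ring <- build_outer_rois(lay$region, jitter_sd = 0.02, seed = 8)
  inner <- build_inner_rois(lay)
  ph3_0 <- chm_row_heights(method_m3(d0, ring, 3), inner)
  ph3_1 <- chm_row_heights(method_m3(d1, ring, 3), inner)
  expect_equal(ph3_1$ph_sfm, ph3_0$ph_sfm, tolerance = 1e-8)
  roi <- measurement_rois(inner)[1, ]
  expect_equal(method_m2(d1, roi), method_m2(d0, roi), tolerance = 1e-12)
})

test_that("ring-fit residuals shrink as the degree rises to the terrain's", {
  lay <- field_layout(4, plot_cols = 2)
  ter <- terrain_spec(default_terrain(lay$region))
  fl <- flight_scenario(-90, FALSE, FALSE, "pre_germination", 1, 63)
  dsm <- render_dsm(lay, ter, NULL, fl, noise_none(), 0.05)
  ring <- build_outer_rois(lay$region, jitter_sd = 0.02, seed = 9)
  pts <- ring_points(dsm, ring)
  rss <- vapply(0:3, function(d)
    attr(fit_polynomial_dtm(pts, d), "rss"), 0)
  expect_true(all(diff(rss) <= 1e-12))
})

test_that("degree selection takes the strongest mean correlation", {
  tab4 <- c(`0` = 0.469, `1` = 0.776, `2` = 0.832, `3` = 0.839, `4` = 0.153)
  expect_equal(select_degree(tab4), 3)
  expect_equal(select_degree(c(`0` = 0.5, `1` = 0.5, `2` = 0.5)), 0)
  expect_equal(select_degree(c(`2` = 0.9, `0` = 0.2)), 2)
  expect_error(select_degree(numeric(0)), "empty")
})

test_that("fitted surfaces round-trip through YAML", {
  surf <- poly_surface(3, rnorm(10), center = c(17.75, 27), scale = c(18, 28))
  p <- tempfile(fileext = ".yaml")
  write_surface_yaml(surf, p)
  back <- read_surface_yaml(p)
  x <- runif(20, 0, 35); y <- runif(20, 0, 54)
  expect_equal(evaluate_surface(back, x, y), evaluate_surface(surf, x, y),
               tolerance = 1e-9)
})
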