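test_that("rasterization burns the geometrically expected cells", {
  g <- grid_template(c(0, 100, 0, 100), 5)
  # a 50 m horizontal line covers exactly 10 cells in one row
  line <- vector_layer(vl_line(cbind(c(0, 50), c(52.5, 52.5))))
  r <- rasterize(line, g, "presence")
  expect_equal(sum(r$values), 10)
  expect_equal(sum(rowSums(r$values) > 0), 1)
  # a 100 x 100 m polygon covers 20 x 20 = 400 cells
  poly <- vector_layer(vl_rect(0, 100, 0, 100))
  expect_equal(sum(rasterize(poly, g)$values), 400)
  # a point burns exactly one cell
  pt <- vector_layer(vl_points(cbind(33, 67)))
  expect_equal(sum(rasterize(pt, g)$values), 1)
  # empty layer: zero raster with a warning, not an error
  expect_warning(r0 <- rasterize(vector_layer(), g), "empty layer")
  expect_equal(sum(r0$values), 0)
})

test_that("focal_sum equals the lattice-point disc count", {
  ones <- raster_grid(matrix(1, 21, 21), 5)
  fs <- focal_sum(ones, 10)
  # cells with centre distance <= 10 m of the centre cell: 13
  expect_equal(fs$values[11, 11], 13, tolerance = 1e-9)
  # brute-force oracle on a random raster, interior and edge cells alike
  set.seed(1)
  v <- matrix(stats::rpois(25 * 25, 2), 25, 25)
  g <- raster_grid(v * 1.0, 5)
  fs2 <- focal_sum(g, 12)
  brute <- matrix(0, 25, 25)
  for (r in 1:25) for (c in 1:25) {
    for (i in 1:25) for (j in 1:25)
      if ((i - r)^2 + (j - c)^2 <= (12 / 5)^2 + 1e-9)
        brute[r, c] <- brute[r, c] + v[i, j]
  }
  expect_equal(fs2$values, brute, tolerance = 1e-8)
  # a single 1 propagates to every cell within the radius
  single <- raster_grid(matrix(c(rep(0, 112), 1, rep(0, 112)), 15, 15), 5)
  fs3 <- focal_sum(single, 20)
  expect_equal(fs3$values[8, 8], 1, tolerance = 1e-9)
  expect_equal(fs3$values[8, 12], 1, tolerance = 1e-9) # 20 m away
  expect_equal(fs3$values[8, 13], 0, tolerance = 1e-9) # 25 m away
  expect_error(focal_sum(ones, 2), ">= cell_size")
})

test_that("euclidean_distance is exact against the brute-force scan", {
  f <- grid_template(c(0, 50, 0, 50), 5)
  f$values[1, 1] <- 1
  d <- euclidean_distance(f)
  expect_equal(d$values[2, 2], 5 * sqrt(2))
  expect_equal(d$values[1, 1], 0)
  set.seed(2)
  v <- matrix(as.numeric(stats::runif(30 * 30) < 0.03), 30, 30)
  v[7, 19] <- 1
  g <- raster_grid(v, 5)
  expect_equal(euclidean_distance(g)$values, brute_force_edt(g))
  expect_error(euclidean_distance(grid_template(c(0, 10, 0, 10), 5)),
               "no feature cells")
})

test_that("log_distance applies the one-cell offset and preserves order", {
  d <- raster_grid(matrix(c(0, 95, 20, 45), 2, 2), 5)
  ld <- log_distance(d)
  expect_equal(ld$values[1, 1], log(5))
  expect_equal(ld$values[2, 1], log(100))
  set.seed(3)
  dv <- matrix(stats::runif(100, 0, 500), 10, 10)
  ld2 <- log_distance(raster_grid(dv, 5))
  expect_equal(order(ld2$values), order(dv))
  expect_error(log_distance(raster_grid(matrix(-1, 2, 2), 5)), "negative")
})

test_that("kernel_density conserves mass and is linear in the weights", {
  tmpl <- grid_template(c(0, 500, 0, 500), 10)
  kd <- kernel_density(cbind(250, 250), 100, tmpl, weights = 1000)
  mass <- sum(kd$values) * 10^2 / 1e6 # per-km^2 back to persons
  expect_lt(abs(mass - 1000) / 1000, 0.01)
  # zero weight -> zero raster
  kd0 <- kernel_density(cbind(250, 250), 100, tmpl, weights = 0)
  expect_equal(sum(kd0$values), 0)
  # two identical points double the field exactly
  kd2 <- kernel_density(rbind(c(250, 250), c(250, 250)), 100, tmpl,
                        weights = c(1000, 1000))
  expect_equal(kd2$values, 2 * kd$values)
  expect_error(kernel_density(cbind(1, 1), 0, tmpl, weights = 1), "radius")
})

test_that("slope_from_dem matches Horn's stencil", {
  cs <- 5
  flat <- raster_grid(matrix(1234, 8, 8), cs)
  expect_equal(max(abs(slope_from_dem(flat)$values)), 0)
  # plane rising 1 m per 1 m eastward: 45 degrees at interior cells
  plane <- raster_grid(outer(1:10, 1:10, function(i, j) j * cs), cs)
  sl <- slope_from_dem(plane)
  expect_equal(sl$values[2:9, 2:9], matrix(45, 8, 8))
  # random smooth DEM vs direct Horn formula, interior cells
  set.seed(4)
  z <- outer(1:12, 1:12, function(i, j) sin(i / 3) * 10 + cos(j / 4) * 8)
  dem <- raster_grid(z, cs)
  sl2 <- slope_from_dem(dem)$values
  for (r in c(2, 6, 11)) for (c in c(2, 7, 11)) {
    dzdx <- ((z[r - 1, c + 1] + 2 * z[r, c + 1] + z[r + 1, c + 1]) -
             (z[r - 1, c - 1] + 2 * z[r, c - 1] + z[r + 1, c - 1])) / (8 * cs)
    dzdy <- ((z[r + 1, c - 1] + 2 * z[r + 1, c] + z[r + 1, c + 1]) -
             (z[r - 1, c - 1] + 2 * z[r - 1, c] + z[r - 1, c + 1])) / (8 * cs)
    expect_equal(sl2[r, c], atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
  }
  expect_error(slope_from_dem(raster_grid(matrix(1, 2, 2), 5)), "3x3")
})

test_that("operations are translation-equivariant", {
  set.seed(5)
  v <- matrix(as.numeric(stats::runif(400) < 0.05), 20, 20)
  v[3, 3] <- 1
  a <- raster_grid(v, 5, origin = c(0, 100))
  b <- raster_grid(v, 5, origin = c(1000, 2100))
  expect_equal(focal_sum(a, 15)$values, focal_sum(b, 15)$values)
  expect_equal(euclidean_distance(a)$values, euclidean_distance(b)$values)
})
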