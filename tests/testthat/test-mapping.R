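const_model <- function(intercept, power = 1, terms = NULL,
                        ppv_transforms = NULL) {
  tr <- structure(list(power = power, branch = 1), class = "lur_transform")
  if (is.null(terms))
    terms <- data.frame(name = character(0), coef = numeric(0))
  structure(list(transform = tr, terms = terms, intercept = intercept,
                 ppv_transforms = ppv_transforms),
            class = "lur_model")
}

test_that("an intercept-only model maps to a constant surface", {
  dom <- grid_template(c(0, 100, 0, 100), 10)
  m <- const_model(log(42))
  pred <- predict_surface(m, list(domain = dom))
  expect_equal(range(pred$values), c(42, 42), tolerance = 1e-12)
})

test_that("a single-term model follows its predictor monotonically", {
  v <- matrix(rep(seq(0, 900, by = 100), each = 10), 10, 10)
  grad <- raster_grid(v, 10)
  m <- const_model(2, terms = data.frame(name = "g", coef = -0.002))
  pred <- predict_surface(m, list(g = grad))
  expect_true(all(diff(pred$values[1, ]) < 0))
  expect_error(predict_surface(m, list(other = grad)), "g")
})

test_that("surface prediction matches scalar evaluation cell by cell", {
  set.seed(1)
  r1 <- raster_grid(matrix(stats::runif(400, 0, 2000), 20, 20), 10)
  r2 <- raster_grid(matrix(stats::runif(400, 0, 5e4), 20, 20), 10)
  m <- const_model(0.12, power = -2,
                   terms = data.frame(name = c("d", "a"),
                                      coef = c(2e-5, -1.5e-6)),
                   ppv_transforms = list(d = list(tag = "identity"),
                                         a = list(tag = "log", eps = 1)))
  pred <- predict_surface(m, list(d = r1, a = r2))
  idx <- cbind(sample(20, 100, TRUE), sample(20, 100, TRUE))
  t_scalar <- 0.12 + 2e-5 * r1$values[idx] - 1.5e-6 * log(r2$values[idx] + 1)
  y_scalar <- ifelse(t_scalar > 0, exp(t_scalar^(-1 / 2)), NA)
  expect_equal(pred$values[idx], y_scalar, tolerance = 1e-9)
})

test_that("the floor rule reproduces reference limits of prediction", {
  r <- raster_grid(matrix(50, 4, 4), 10)
  # min observed / sqrt(2), at one-decimal rounding
  expect_equal(round(clip_predictions(r, 22, 96)$floor, 1), 15.6)
  expect_equal(round(clip_predictions(r, 23, 89)$floor, 1), 16.3)
  expect_equal(round(clip_predictions(r, 17, 268)$floor, 1), 12.0)
  expect_equal(round(clip_predictions(r, 49, 336)$floor, 1), 34.6)
})

test_that("clipping is idempotent and conserves cell counts", {
  set.seed(2)
  v <- matrix(stats::runif(900, 0, 200), 30, 30)
  v[sample(900, 5)] <- NA # non-invertible cells count as enlarged
  r <- raster_grid(v, 5)
  cl <- clip_predictions(r, 40, 120)
  expect_equal(cl$n_enlarged,
               sum(is.na(v) | v < 40 / sqrt(2)))
  expect_equal(cl$n_truncated, sum(v > 1.2 * 120, na.rm = TRUE))
  untouched <- sum(!is.na(v) & v >= 40 / sqrt(2) & v <= 1.2 * 120)
  expect_equal(cl$n_enlarged + cl$n_truncated + untouched, cl$n_cells)
  expect_true(all(cl$raster$values >= cl$floor - 1e-12 &
                  cl$raster$values <= cl$ceiling + 1e-12))
  # idempotence
  cl2 <- clip_predictions(cl$raster, 40, 120)
  expect_equal(cl2$raster$values, cl$raster$values)
  expect_equal(cl2$n_truncated, 0)
  # raising the observed maximum can only reduce the truncated fraction
  cl3 <- clip_predictions(r, 40, 160)
  expect_lte(cl3$frac_truncated, cl$frac_truncated)
  # a raster already inside the limits is unchanged
  inr <- raster_grid(matrix(stats::runif(100, 50, 100), 10, 10), 5)
  cl4 <- clip_predictions(inr, 60, 120)
  expect_equal(cl4$frac_enlarged, 0)
  expect_equal(cl4$frac_truncated, 0)
  expect_equal(cl4$raster$values, inr$values)
})

test_that("pathological clip inputs are refused", {
  r <- raster_grid(matrix(1, 2, 2), 5)
  expect_error(clip_predictions(r, 0, 10), "positive")
  expect_error(clip_predictions(r, 10, 10), "exceed")
})
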