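make_fitted_model <- function(n = 23, noise = 0.1, seed = 1) {
  set.seed(seed)
  des <- data.frame(station_id = sprintf("S%02d", 1:n),
                    a = stats::rnorm(n), b = stats::rnorm(n))
  y <- exp(1 + 0.8 * des$a - 0.5 * des$b + stats::rnorm(n, 0, noise))
  model <- forward_select(des, y, c(a = "+", b = "-"),
                          transform = log_transform())
  list(design = des, y = y, model = model)
}

test_that("noiseless fits have perfectly stable coefficients", {
  n <- 20
  des <- data.frame(station_id = sprintf("S%02d", 1:n),
                    a = stats::rnorm(n), b = stats::rnorm(n))
  y <- exp(1 + 0.8 * des$a - 0.5 * des$b) # no noise at all
  model <- forward_select(des, y, c(a = "+", b = "-"),
                          transform = log_transform())
  stab <- loocv_coefficient_stability(des, model)
  expect_equal(stab$cv, rep(0, nrow(stab)), tolerance = 1e-8)
  expect_equal(stab$min, stab$full_coef, tolerance = 1e-8)
  expect_equal(stab$max, stab$full_coef, tolerance = 1e-8)
  expect_true(all(stab$sign_consistent))
})

test_that("duplicating rows halves leverage and shrinks coefficient CVs", {
  f <- make_fitted_model(noise = 0.3, seed = 2)
  stab1 <- loocv_coefficient_stability(f$design, f$model)
  dd <- rbind(f$design, f$design)
  model2 <- f$model
  model2$y <- c(f$y, f$y)
  stab2 <- loocv_coefficient_stability(dd, model2)
  expect_true(all(stab2$cv < stab1$cv))
})

test_that("morans_i matches the brute-force double loop and ape", {
  set.seed(3)
  n <- 23
  coords <- cbind(stats::runif(n, 0, 1000), stats::runif(n, 0, 1000))
  z <- stats::rnorm(n)
  res <- morans_i(z, coords)
  W <- 1 / as.matrix(stats::dist(coords)); diag(W) <- 0
  W <- W / rowSums(W)
  expect_equal(res$I, brute_force_moran(z, W), tolerance = 1e-12)
  expect_equal(res$expected, -1 / (n - 1))
  skip_if_not_installed("ape")
  ref <- ape::Moran.I(z, W)
  expect_equal(res$I, ref$observed, tolerance = 1e-10)
  expect_equal(res$sd, ref$sd, tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("morans_i is calibrated under independence", {
  set.seed(4)
  n <- 23
  coords <- cbind(stats::runif(n, 0, 1000), stats::runif(n, 0, 1000))
  sims <- replicate(400, {
    r <- morans_i(stats::rnorm(n), coords)
    c(I = r$I, rej = r$p_value < 0.05)
  })
  expect_lt(abs(mean(sims["I", ]) - (-1 / (n - 1))), 0.005)
  expect_gt(mean(sims["rej", ]), 0.01)
  expect_lt(mean(sims["rej", ]), 0.10)
})

test_that("a spatial gradient in residuals is detected", {
  set.seed(5)
  n <- 30
  coords <- cbind(stats::runif(n, 0, 1000), stats::runif(n, 0, 1000))
  z <- coords[, 1] / 1000 + stats::rnorm(n, 0, 0.2)
  res <- morans_i(z, coords)
  expect_gt(res$I, 0)
  expect_lt(res$p_value, 0.05)
  # permutation p agrees in conclusion
  resp <- morans_i(z, coords, p_method = "permutation", n_perm = 499)
  expect_lt(resp$p_value, 0.05)
})

test_that("morans_i is invariant to shifting and scaling residuals", {
  set.seed(6)
  n <- 15
  coords <- cbind(stats::runif(n), stats::runif(n))
  z <- stats::rnorm(n)
  a <- morans_i(z, coords)
  b <- morans_i(5 + 3 * z, coords)
  expect_equal(a$I, b$I, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("degenerate diagnostics inputs are refused", {
  coords <- cbind(c(0, 0, 1, 2, 3), c(0, 0, 1, 2, 3))
  expect_error(morans_i(stats::rnorm(5), coords), "jitter")
  cc <- cbind(1:5, 1:5)
  expect_error(morans_i(rep(1, 5), cc), "zero-variance")
  expect_error(morans_i(stats::rnorm(4), cc[1:4, ]), "at least 5")
  # knn weights tolerate coincident points
  expect_s3_class(morans_i(stats::rnorm(5), coords, weights = "knn", k = 2),
                  "moran_result")
})
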