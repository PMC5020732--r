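sim_corr_hourly <- function(n = 8760, k = 3, rho = 0.9, seed = 1,
                            means = 50 + 10 * seq_len(k)) {
  set.seed(seed)
  z <- stats::rnorm(n)
  sapply(seq_len(k), function(j)
    means[j] + 10 * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n)))
}

test_that("a gap-free matrix passes through every run unchanged", {
  ts <- hourly_timestamps()
  Y <- sim_corr_hourly(n = 8760, k = 2, seed = 2)
  imp <- em_bootstrap_impute(Y, timestamps = ts, n_runs = 3, seed = 1)
  for (r in 1:3) expect_identical(imp$runs[[r]], Y)
})

test_that("imputed station means agree with complete-data means at 28% MCAR", {
  ts <- hourly_timestamps()
  Y <- sim_corr_hourly(seed = 3)
  set.seed(4)
  miss <- matrix(stats::runif(length(Y)) < 0.28, nrow(Y), ncol(Y))
  Ym <- Y; Ym[miss] <- NA
  imp <- em_bootstrap_impute(Ym, timestamps = ts, n_runs = 10, seed = 5)
  avg <- Reduce(`+`, imp$runs) / imp$n_runs
  mc_se <- apply(Y, 2, stats::sd) / sqrt(nrow(Y))
  expect_true(all(abs(colMeans(avg) - colMeans(Y)) <= 2 * mc_se))
  # observed values are bitwise untouched in every run
  for (r in seq_along(imp$runs))
    expect_identical(imp$runs[[r]][!miss], Y[!miss])
})

test_that("imputation error is monotone in the missingness rate", {
  ts <- hourly_timestamps()
  Y <- sim_corr_hourly(seed = 6)
  mae <- sapply(c(0.10, 0.30, 0.50), function(rate) {
    set.seed(7)
    miss <- matrix(stats::runif(length(Y)) < rate, nrow(Y), ncol(Y))
    Ym <- Y; Ym[miss] <- NA
    imp <- em_bootstrap_impute(Ym, timestamps = ts, n_runs = 3, seed = 8)
    avg <- Reduce(`+`, imp$runs) / imp$n_runs
    mean(abs(avg[miss] - Y[miss]))
  })
  expect_true(all(diff(mae) >= 0))
})

test_that("averaging across runs reduces station-mean error vs single runs", {
  ts <- hourly_timestamps()
  Y <- sim_corr_hourly(seed = 9)
  set.seed(10)
  miss <- matrix(stats::runif(length(Y)) < 0.28, nrow(Y), ncol(Y))
  Ym <- Y; Ym[miss] <- NA
  imp <- em_bootstrap_impute(Ym, timestamps = ts, n_runs = 10, seed = 11)
  truth <- colMeans(Y)
  run_mse <- sapply(imp$runs, function(m) mean((colMeans(m) - truth)^2))
  avg_mse <- mean((colMeans(Reduce(`+`, imp$runs) / 10) - truth)^2)
  expect_lt(avg_mse, mean(run_mse))
})

test_that("seasonal means split the year at April and October", {
  ts <- hourly_timestamps()
  mon <- as.integer(format(ts, "%m"))
  const <- matrix(4.2, 8760, 2)
  res <- structure(list(runs = list(const), observed = !is.na(const),
                        timestamps = ts, n_runs = 1,
                        station_ids = c("a", "b")),
                   class = "imputation_result")
  sm <- seasonal_means(res)
  expect_equal(unlist(sm[1, c("annual", "cooler", "warmer")]),
               c(annual = 4.2, cooler = 4.2, warmer = 4.2))
  two <- matrix(ifelse(mon %in% 4:9, 1, 3), 8760, 2)
  res2 <- res; res2$runs <- list(two)
  sm2 <- seasonal_means(res2)
  expect_equal(sm2$warmer[1], 1)
  expect_equal(sm2$cooler[1], 3)
  expect_true(sm2$annual[1] > 1 && sm2$annual[1] < 3)
  # partial years are refused
  res3 <- res; res3$timestamps <- ts[1:5000]; res3$runs <- list(const[1:5000, ])
  expect_error(seasonal_means(res3), "full-year")
})

test_that("degenerate inputs are refused with informative errors", {
  ts <- hourly_timestamps()
  Y <- sim_corr_hourly(k = 2, seed = 12)
  Y[, 2] <- NA
  expect_error(em_bootstrap_impute(Y, timestamps = ts), "all-missing")
  Y2 <- sim_corr_hourly(k = 2, seed = 13)
  Y2[1:8500, 2] <- NA
  expect_error(em_bootstrap_impute(Y2, timestamps = ts), "10%")
  expect_error(em_bootstrap_impute(Y2[, 1, drop = FALSE], timestamps = ts),
               "2 stations")
})
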