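test_that("response transform keeps the log for log-normal data", {
  set.seed(1)
  y <- exp(stats::rnorm(50, 3, 0.5))
  tr <- select_response_transform(y)
  expect_equal(tr$power, 1)
  # the candidate set carries the seasonal-model exponents
  expect_true(all(c(-4, -3, -2, -1, 2, 3) %in%
                  eval(formals(select_response_transform)$candidates)))
  expect_error(select_response_transform(rep(2, 20)), "constant")
  expect_error(select_response_transform(c(-1, 1:19)), "positive")
})

test_that("response transform picks a power when log(y) is non-normal", {
  set.seed(2)
  # log y is the reciprocal of a normal, so (log y)^-1 is normal while
  # log y itself is strongly skewed
  t <- stats::rnorm(60, 4, 1)
  y <- exp(1 / t)
  tr <- select_response_transform(y)
  expect_true(tr$power != 1)
  expect_gt(stats::shapiro.test(log(y)^tr$power)$p.value, tr$shapiro_p_log)
  # round trip through the chosen transform
  yt <- transform_apply(tr, y)
  expect_equal(transform_invert(tr, yt), y, tolerance = 1e-10)
})

test_that("linearization recovers the generating transform", {
  set.seed(3)
  x <- exp(stats::rnorm(60, 3, 1))
  des <- data.frame(lin = 2 * x + stats::rnorm(60, 0, 0.01),
                    lg = x, p01 = x, const = 5)
  resp_lg <- 3 * log(x + min(x) / 2)
  resp01 <- 2 * x^0.1
  lin1 <- linearize_ppvs(des, 2 * des$lin, "lin")
  expect_equal(lin1$transforms$lin$tag, "identity")
  lin2 <- linearize_ppvs(des, resp_lg, "lg")
  expect_equal(lin2$transforms$lg$tag, "log")
  lin3 <- linearize_ppvs(des, resp01, "p01")
  expect_equal(lin3$transforms$p01$tag, "pow0.1")
  lin4 <- linearize_ppvs(des, resp_lg, c("lg", "const"))
  expect_equal(lin4$excluded, "const")
})

test_that("loocv_r2 equals brute-force refitting", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 15
    des <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                      c = stats::rnorm(n))
    y <- 1 + des$a - 2 * des$b + stats::rnorm(n)
    expect_equal(loocv_r2(des, y, c("a", "b", "c")),
                 brute_force_loocv(des, y, c("a", "b", "c")),
                 tolerance = 1e-10)
  }
  # exact linear data scores 1
  des <- data.frame(a = 1:12)
  expect_equal(loocv_r2(des, 3 + 2 * des$a, "a"), 1)
  # pure-noise predictors score at or below zero in expectation
  set.seed(5)
  sims <- replicate(200, {
    d <- data.frame(a = stats::rnorm(23))
    loocv_r2(d, stats::rnorm(23), "a")
  })
  expect_lt(mean(sims), 0)
  expect_error(loocv_r2(data.frame(a = rep(1, 10), b = 1:10),
                        stats::rnorm(10), c("a", "b")), "singular")
})

test_that("vif matches the closed form", {
  set.seed(21)
  # centred mutually orthogonal columns (VIF regressions carry an
  # intercept, so orthogonality must hold after centering): all VIFs are 1
  q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(60), 20, 3))))[, 2:4]
  des <- as.data.frame(q)
  names(des) <- c("V1", "V2", "V3")
  expect_equal(unname(vif(des, c("V1", "V2", "V3"))), rep(1, 3),
               tolerance = 1e-10)
  # exact pairwise correlation 0.9: VIF = 1/(1 - 0.81)
  x2 <- 0.9 * q[, 1] + sqrt(1 - 0.81) * q[, 2]
  des2 <- data.frame(a = q[, 1], b = x2)
  expect_equal(unname(vif(des2, c("a", "b"))), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-10)
  # single variable: 1 by convention; exact collinearity: Inf
  expect_equal(unname(vif(des2, "a")), 1)
  des3 <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_equal(unname(vif(des3, c("a", "b"))), c(Inf, Inf))
})

test_that("forward selection recovers a planted model under its gates", {
  set.seed(6)
  n <- 40
  X <- matrix(stats::rnorm(n * 52), n, 52,
              dimnames = list(NULL, c("x1", "x2", paste0("d", 1:50))))
  y <- exp(1 + 2 * X[, "x1"] - 1 * X[, "x2"] + stats::rnorm(n, 0, 0.01))
  des <- as.data.frame(X)
  priors <- stats::setNames(rep("none", 52), colnames(X))
  priors[c("x1", "x2")] <- c("+", "-")
  m <- forward_select(des, y, priors, transform = log_transform())
  expect_true(all(c("x1", "x2") %in% m$terms$name))
  acc <- m$trace[m$trace$decision == "accepted", ]
  expect_equal(acc$candidate[1:2], c("x1", "x2"))
  expect_gt(m$terms$coef[m$terms$name == "x1"], 0)
  expect_lt(m$terms$coef[m$terms$name == "x2"], 0)
  expect_true(all(audit_selection(m)))
  expect_equal(m$cap, ceiling(sqrt(40)))
})

test_that("sign-prior violations are rejected and visible in the trace", {
  set.seed(7)
  n <- 23
  des <- data.frame(a = stats::rnorm(n))
  y <- exp(2 - 1.5 * des$a + stats::rnorm(n, 0, 0.05))
  # prior says "+" but the true effect is negative: empty model, traced
  m <- forward_select(des, y, c(a = "+"), transform = log_transform())
  expect_equal(nrow(m$terms), 0)
  expect_true(any(grepl("^sign\\(a\\)", m$trace$decision)))
  expect_equal(m$cap, 5) # ceiling(sqrt(23))
  # with the correct prior the variable is admitted
  m2 <- forward_select(des, y, c(a = "-"), transform = log_transform())
  expect_equal(m2$terms$name, "a")
})

test_that("residual-normality gate is calibrated and has power", {
  set.seed(8)
  flags <- replicate(200,
    residual_normality(stats::rnorm(23))$flagged)
  expect_gt(mean(flags), 0.005)
  expect_lt(mean(flags), 0.12) # ~ alpha = 0.05
  heavy <- replicate(100,
    residual_normality(stats::rt(23, df = 2))$flagged)
  expect_gt(mean(heavy), 0.5)
  expect_error(residual_normality(rep(0, 23)), "degenerate")
  expect_error(residual_normality(c(0.1, 0.2)), "at least 3")
})
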