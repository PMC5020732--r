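# Multiple imputation of gappy hourly monitoring series: a multivariate-
# normal EM fitted to a bootstrap resample of the rows (stations jointly,
# plus fully-observed harmonic time covariates), then each missing cell is
# imputed by its conditional mean plus a draw from the conditional
# covariance. The whole procedure is repeated n_runs times and station
# means are averaged across runs.

#' Harmonic and calendar covariates for hourly timestamps
#'
#' Sin/cos of hour-of-day and day-of-year plus month indicators (February
#' through December; January is the reference to keep the covariance
#' nonsingular).
#'
#' @param timestamps POSIXct vector.
#' @return numeric matrix with one row per timestamp.
#' @export
time_covariates <- function(timestamps) {
  hr <- as.integer(format(timestamps, "%H"))
  doy <- as.integer(format(timestamps, "%j"))
  mon <- as.integer(format(timestamps, "%m"))
  m <- cbind(sin_hod = sin(2 * pi * hr / 24), cos_hod = cos(2 * pi * hr / 24),
             sin_doy = sin(2 * pi * doy / 365.25),
             cos_doy = cos(2 * pi * doy / 365.25))
  for (k in 2:12) m <- cbind(m, (mon == k) * 1)
  colnames(m)[5:15] <- sprintf("mon_%02d", 2:12)
  m
}

miss_patterns <- function(M) {
  # group rows by their missingness pattern over the imputable columns
  key <- apply(M, 1L, function(r) paste(as.integer(r), collapse = ""))
  split(seq_len(nrow(M)), key)
}

em_mvnorm <- function(Z, miss, tol, max_iter, ridge) {
  # EM for a multivariate normal with values missing in (some of) the
  # columns; `miss` is the logical missingness matrix for Z
  p <- ncol(Z)
  mu <- colMeans(Z, na.rm = TRUE)
  Zc <- Z
  Zc[miss] <- matrix(mu, nrow(Z), p, byrow = TRUE)[miss]
  Sigma <- stats::cov(Zc)
  dv <- pmax(diag(Sigma), 1e-12)
  Sigma <- Sigma + diag(ridge * dv, p)
  groups <- miss_patterns(miss)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      m <- which(miss[g[1L], ])
      o <- which(!miss[g[1L], ])
      Zo <- Z[g, o, drop = FALSE]
      n_g <- length(g)
      Soo_inv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      dev <- sweep(Zo, 2L, mu[o])
      # observed-data log likelihood for this pattern
      ll <- ll - 0.5 * n_g * (length(o) * log(2 * pi) -
              determinant(Soo_inv, logarithm = TRUE)$modulus[1]) -
            0.5 * sum((dev %*% Soo_inv) * dev)
      Zfull <- matrix(0, n_g, p)
      Zfull[, o] <- Zo
      if (length(m)) {
        B <- Sigma[m, o, drop = FALSE] %*% Soo_inv
        cond_mean <- matrix(mu[m], n_g, length(m), byrow = TRUE) +
          dev %*% t(B)
        Zfull[, m] <- cond_mean
        Cm <- Sigma[m, m, drop = FALSE] -
          B %*% Sigma[o, m, drop = FALSE]
        S2[m, m] <- S2[m, m] + n_g * Cm
      }
      S1 <- S1 + colSums(Zfull)
      S2 <- S2 + crossprod(Zfull)
    }
    n <- nrow(Z)
    mu <- S1 / n
    Sigma <- S2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    dv <- pmax(diag(Sigma), 1e-12)
    Sigma <- Sigma + diag(ridge * dv, p)
    trace <- c(trace, ll)
    rel <- abs(ll - ll_old) / (abs(ll_old) + 1e-12)
    if (is.finite(ll_old) && rel < tol)
      return(list(mu = mu, Sigma = Sigma, iter = it, loglik = trace,
                  converged = TRUE))
    ll_old <- ll
  }
  stop("EM did not converge in ", max_iter,
       " iterations; last relative log-likelihood changes: ",
       paste(signif(abs(diff(utils::tail(trace, 4))) /
                    (abs(utils::tail(trace, 4)[-4]) + 1e-12), 3),
             collapse = ", "))
}

impute_with_params <- function(Y, X, miss, mu, Sigma, draw = TRUE) {
  # conditional-mean + noise imputation of Y's missing cells under the
  # fitted joint normal for Z = [Y, X]
  out <- Y
  p_y <- ncol(Y)
  Z <- cbind(Y, X)
  groups <- miss_patterns(miss)
  for (g in groups) {
    m <- which(miss[g[1L], ])
    if (!length(m)) next
    o_y <- which(!miss[g[1L], ])
    o <- c(o_y, p_y + seq_len(ncol(X)))
    n_g <- length(g)
    Soo_inv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
    B <- Sigma[m, o, drop = FALSE] %*% Soo_inv
    dev <- sweep(Z[g, o, drop = FALSE], 2L, mu[o])
    cond_mean <- matrix(mu[m], n_g, length(m), byrow = TRUE) + dev %*% t(B)
    if (draw) {
      Cm <- Sigma[m, m, drop = FALSE] - B %*% Sigma[o, m, drop = FALSE]
      Cm <- (Cm + t(Cm)) / 2
      ch <- tryCatch(chol(Cm), error = function(e)
        chol(Cm + diag(1e-8 * max(diag(Cm), 1e-12), nrow(Cm))))
      cond_mean <- cond_mean +
        matrix(stats::rnorm(n_g * length(m)), n_g) %*% ch
    }
    out[g, m] <- cond_mean
  }
  out
}

#' EM-with-bootstrap multiple imputation of hourly station series
#'
#' For each of `n_runs` runs: bootstrap the rows, fit a multivariate-normal
#' EM on stations plus time covariates to convergence (relative observed-
#' data log-likelihood change below `tol`, at most `max_iter` iterations),
#' then impute each missing cell of the *original* matrix by its
#' conditional mean plus a draw from the conditional variance. Observed
#' cells are never altered.
#'
#' @param y hours x stations numeric matrix with `NA` gaps (one pollutant).
#' @param timestamps POSIXct vector matching the rows; used to build
#'   covariates when `covariates` is NULL.
#' @param covariates fully observed covariate matrix (see
#'   [time_covariates()]); pass `NULL` with `timestamps` for the default.
#' @param n_runs number of imputation runs to average (default 10).
#' @param seed integer RNG seed; the whole procedure is deterministic
#'   given it.
#' @param tol,max_iter EM convergence control.
#' @param ridge relative ridge added to the covariance diagonal for
#'   numerical stability.
#' @param clip_negative clip imputed concentrations at zero.
#' @param log_scale run the EM on log(y + 1) and back-transform (optional;
#'   default works on the raw scale, mirroring the normality assumption of
#'   the classical EM imputer).
#' @return an object of class `imputation_result`: list with `runs` (list
#'   of completed matrices), `observed` mask, `timestamps`, `n_runs`,
#'   `em_iterations`.
#' @export
em_bootstrap_impute <- function(y, timestamps = NULL, covariates = NULL,
                                n_runs = 10L, seed = 1L, tol = 1e-6,
                                max_iter = 200L, ridge = 1e-6,
                                clip_negative = TRUE, log_scale = FALSE) {
  y <- as.matrix(y)
  if (ncol(y) < 2L) stop("need at least 2 stations for joint imputation")
  obs_frac <- colMeans(!is.na(y))
  if (any(obs_frac == 0))
    stop("all-missing station column: ",
         paste(colnames(y)[obs_frac == 0], collapse = ", "))
  if (any(obs_frac < 0.10))
    stop("station with < 10% observed values: ",
         paste(colnames(y)[obs_frac < 0.10], collapse = ", "))
  if (is.null(covariates)) {
    if (is.null(timestamps)) stop("supply timestamps or covariates")
    covariates <- time_covariates(timestamps)
  }
  X <- as.matrix(covariates)
  if (anyNA(X)) stop("covariates must be fully observed")
  Ywork <- if (log_scale) log(pmax(y, 0) + 1) else y
  miss <- is.na(y)
  set.seed(seed)
  n <- nrow(y)
  runs <- vector("list", n_runs)
  iters <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    if (any(miss)) {
      bi <- sample.int(n, n, replace = TRUE)
      fit <- em_mvnorm(cbind(Ywork, X)[bi, , drop = FALSE],
                       cbind(miss, matrix(FALSE, n, ncol(X)))[bi, ,
                                                              drop = FALSE],
                       tol = tol, max_iter = max_iter, ridge = ridge)
      compl <- impute_with_params(Ywork, X, miss, fit$mu, fit$Sigma)
      iters[r] <- fit$iter
    } else {
      compl <- Ywork
      iters[r] <- 0L
    }
    if (log_scale) {
      compl_raw <- exp(compl) - 1
      compl_raw[!miss] <- y[!miss]
      compl <- compl_raw
    }
    if (clip_negative) compl[miss & compl < 0] <- 0
    runs[[r]] <- compl
  }
  structure(list(runs = runs, observed = !miss, timestamps = timestamps,
                 n_runs = n_runs, em_iterations = iters,
                 station_ids = colnames(y)),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %d runs, %d x %d matrix, %.1f%% imputed\n",
              x$n_runs, nrow(x$runs[[1]]), ncol(x$runs[[1]]),
              100 * mean(!x$observed)))
  invisible(x)
}

#' Annual and seasonal station means from completed runs
#'
#' Means over all 8760 hours (annual), the October-March hours (cooler) and
#' the April-September hours (warmer), averaged across imputation runs.
#'
#' @param result an `imputation_result` with full-year hourly timestamps.
#' @param warmer_months integer months of the warmer season (default 4:9).
#' @return data.frame: station_id, annual, cooler, warmer.
#' @export
seasonal_means <- function(result, warmer_months = 4:9) {
  ts <- result$timestamps
  if (is.null(ts) || length(ts) != 8760L)
    stop("seasonal_means requires a full-year hourly series (8760 rows)")
  season <- season_of(ts, warmer_months)
  per_run <- lapply(result$runs, function(m) {
    cbind(annual = colMeans(m),
          cooler = colMeans(m[season == "cooler", , drop = FALSE]),
          warmer = colMeans(m[season == "warmer", , drop = FALSE]))
  })
  avg <- Reduce(`+`, per_run) / length(per_run)
  ids <- result$station_ids
  if (is.null(ids)) ids <- sprintf("ST%02d", seq_len(nrow(avg)))
  data.frame(station_id = ids, annual = avg[, "annual"],
             cooler = avg[, "cooler"], warmer = avg[, "warmer"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hourly series data.frame to hours x stations matrix
#'
#' @param series long data.frame (station_id, timestamp, pollutant columns).
#' @param pollutant which pollutant column to extract.
#' @return list with `y` (matrix), `timestamps`.
#' @export
series_to_matrix <- function(series, pollutant = "no") {
  ids <- unique(series$station_id)
  ts <- sort(unique(series$timestamp))
  y <- matrix(NA_real_, length(ts), length(ids),
              dimnames = list(NULL, ids))
  ti <- match(series$timestamp, ts)
  si <- match(series$station_id, ids)
  y[cbind(ti, si)] <- series[[pollutant]]
  list(y = y, timestamps = ts)
}
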