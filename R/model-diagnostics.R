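# Post-fit diagnostics: coefficient stability across leave-one-out refits,
# and global Moran's I for spatial autocorrelation of model residuals.

#' Coefficient stability across leave-one-out refits
#'
#' Refits the selected model once per station with that station held out
#' and summarizes each coefficient's minimum, maximum and coefficient of
#' variation (sd / |mean|) across the refits; a model is more stable when
#' the CVs are small and every coefficient keeps its direction of effect.
#'
#' @param design design data.frame used for the fit (with station_id).
#' @param model a `lur_model` with at least one term.
#' @return data.frame of class `stability_report`: term, full_coef, min,
#'   max, mean, cv, sign_consistent.
#' @export
loocv_coefficient_stability <- function(design, model) {
  vars <- model$terms$name
  if (!length(vars)) stop("model has no terms to check")
  yt <- transform_apply(model$transform, model$y)
  n <- nrow(design)
  coefs <- matrix(NA_real_, n, length(vars) + 1L,
                  dimnames = list(NULL, c("(Intercept)", vars)))
  for (i in seq_len(n)) {
    st <- fit_stats(design[-i, , drop = FALSE], yt[-i], vars)
    if (is.null(st)) {
      id <- if ("station_id" %in% names(design)) design$station_id[i] else i
      stop("leave-one-out refit singular when omitting station ", id)
    }
    coefs[i, ] <- st$coef[colnames(coefs)]
  }
  full <- c(model$intercept, model$terms$coef)
  out <- data.frame(
    term = colnames(coefs),
    full_coef = full,
    min = apply(coefs, 2, min),
    max = apply(coefs, 2, max),
    mean = colMeans(coefs),
    cv = apply(coefs, 2, stats::sd) / abs(colMeans(coefs)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$sign_consistent <- sign(out$min) == sign(out$max)
  class(out) <- c("stability_report", class(out))
  out
}

moran_weights <- function(coords, scheme = c("inverse_distance", "knn"),
                          k = 5, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  if (scheme == "inverse_distance") {
    if (any(d[upper.tri(d)] == 0))
      stop("coincident points give infinite inverse-distance weights; ",
           "jitter the coordinates or use knn weights")
    W <- 1 / d
    diag(W) <- 0
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1L)]
      W[i, nb] <- 1
    }
  }
  if (row_standardize) W <- W / rowSums(W)
  W
}

#' Global Moran's I on residuals
#'
#' I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centred
#' residuals. Expectation under the null is -1/(n-1); the p-value comes
#' from the normal approximation under the randomization assumption, or
#' from a permutation test.
#'
#' @param residuals numeric vector (n >= 5, non-constant).
#' @param coords two-column matrix / data.frame of station coordinates.
#' @param weights `"inverse_distance"` (default) or `"knn"`.
#' @param k neighbours for knn weights.
#' @param row_standardize row-standardize the weight matrix (default TRUE).
#' @param p_method `"normal"` (randomization variance) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param seed RNG seed for the permutation test.
#' @return list of class `moran_result`: `I`, `expected`, `variance`,
#'   `sd`, `p_value`, `weights`.
#' @export
morans_i <- function(residuals, coords, weights = c("inverse_distance", "knn"),
                     k = 5, row_standardize = TRUE,
                     p_method = c("normal", "permutation"), n_perm = 999,
                     seed = 1L) {
  weights <- match.arg(weights)
  p_method <- match.arg(p_method)
  n <- length(residuals)
  if (n < 5L) stop("need at least 5 stations")
  if (stats::sd(residuals) == 0) stop("zero-variance residuals")
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  W <- moran_weights(coords, weights, k, row_standardize)
  z <- residuals - mean(residuals)
  S0 <- sum(W)
  I <- (n / S0) * sum(W * tcrossprod(z)) / sum(z^2)
  EI <- -1 / (n - 1)
  # randomization variance (Cliff & Ord)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
         b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
        ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  if (p_method == "normal") {
    zscore <- (I - EI) / sqrt(VI)
    p <- 2 * stats::pnorm(abs(zscore), lower.tail = FALSE)
  } else {
    set.seed(seed)
    perm <- replicate(n_perm, {
      zs <- z[sample.int(n)]
      (n / S0) * sum(W * tcrossprod(zs)) / sum(zs^2)
    })
    p <- (1 + sum(abs(perm - EI) >= abs(I - EI))) / (n_perm + 1)
  }
  structure(list(I = I, expected = EI, variance = VI, sd = sqrt(VI),
                 p_value = p,
                 weights = sprintf("%s%s", weights,
                                   if (row_standardize) " (row-standardized)"
                                   else "")),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<moran_result> I = %.4f (E[I] = %.4f, sd %.4f), p = %.3g [%s]\n",
              x$I, x$expected, x$sd, x$p_value, x$weights))
  invisible(x)
}
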