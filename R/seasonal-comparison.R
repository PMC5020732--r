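# Seasonal stability of the predicted spatial pattern: sample random
# locations over the mapped domain and correlate the annual, cooler-season
# and warmer-season surfaces there, choosing Pearson or Spearman per pair
# according to a Shapiro-Wilk normality gate.

#' Sample distinct random locations over a raster domain
#'
#' Uniform over the unmasked (non-`NA`) cells, without replacement at cell
#' resolution; returns cell-centre coordinates. Deterministic given the
#' seed.
#'
#' @param domain a `raster_grid`; `NA` cells are excluded.
#' @param n number of locations (>= 2).
#' @param seed integer RNG seed.
#' @return data.frame with columns x, y.
#' @export
sample_locations <- function(domain, n = 1000L, seed = 1L) {
  if (n < 2L) stop("n must be >= 2")
  free <- which(!is.na(domain$values))
  if (length(free) < n)
    stop(sprintf("requested %d locations but only %d unmasked cells", n,
                 length(free)))
  set.seed(seed)
  cells <- if (length(free) == n) free else free[sample.int(length(free), n)]
  nr <- nrow(domain$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cs <- domain$cell_size
  data.frame(x = domain$origin[1] + (col - 0.5) * cs,
             y = domain$origin[2] - (row - 0.5) * cs)
}

shapiro_gate_p <- function(x) {
  # shapiro.test accepts at most 5000 values; use a deterministic thinning
  if (length(x) > 5000L) x <- x[round(seq(1L, length(x), length.out = 5000L))]
  stats::shapiro.test(x)$p.value
}

#' Correlate predicted surfaces at sampled locations
#'
#' Extracts each surface at the points, tests each series for normality
#' (Shapiro-Wilk at `alpha`), and correlates each pair with Pearson when
#' both series pass and Spearman otherwise.
#'
#' @param maps named list of `raster_grid`s on a shared grid (e.g. annual,
#'   cooler, warmer).
#' @param points data.frame with x, y (e.g. from [sample_locations()]).
#' @param alpha normality gate level.
#' @return list of class `seasonal_correlation`: `correlation` (matrix),
#'   `method` (matrix of "pearson"/"spearman"), `shapiro_p`, `values`
#'   (data.frame of sampled values), `n`.
#' @export
correlate_predictions <- function(maps, points, alpha = 0.05) {
  stopifnot(length(maps) >= 2L, !is.null(names(maps)))
  spec <- vapply(maps, function(g) c(dim(g$values), g$cell_size, g$origin),
                 numeric(5))
  if (any(apply(spec, 1, function(r) max(r) - min(r)) > 1e-9))
    stop("all maps must share the same grid spec")
  vals <- as.data.frame(lapply(maps, function(g)
    extract_values(g, points$x, points$y)))
  names(vals) <- names(maps)
  const <- vapply(vals, function(v) stats::sd(v, na.rm = TRUE) == 0,
                  logical(1))
  if (any(const))
    stop("constant predicted series, correlation undefined: ",
         paste(names(vals)[const], collapse = ", "))
  sw <- vapply(vals, shapiro_gate_p, numeric(1))
  k <- length(maps)
  cm <- matrix(1, k, k, dimnames = list(names(maps), names(maps)))
  mm <- matrix("", k, k, dimnames = dimnames(cm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { mm[i, j] <- "-"; next }
    method <- if (sw[i] >= alpha && sw[j] >= alpha) "pearson" else "spearman"
    cm[i, j] <- stats::cor(vals[[i]], vals[[j]], method = method,
                           use = "complete.obs")
    mm[i, j] <- method
  }
  structure(list(correlation = cm, method = mm, shapiro_p = sw,
                 values = vals, n = nrow(points)),
            class = "seasonal_correlation")
}

#' @export
print.seasonal_correlation <- function(x, ...) {
  cat(sprintf("<seasonal_correlation> %d locations\n", x$n))
  print(round(x$correlation, 3))
  cat("  methods:\n")
  print(x$method, quote = FALSE)
  invisible(x)
}
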