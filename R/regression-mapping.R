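# Regression mapping: render a fitted model over the full raster domain,
# then apply the floor rule (limit of prediction = minimum observed
# concentration / sqrt(2)) and the ceiling rule (120% of the maximum
# observed concentration), reporting the fractions of cells affected.

#' Predict a concentration surface from a fitted model
#'
#' Evaluates the linear model on the transformed scale cell by cell (after
#' applying each term's predictor transform and replacing nodata with
#' zero), then inverts the response transform back to ppb. Cells where the
#' inversion is undefined (e.g. non-positive transformed values under an
#' even power) are returned as `NA` and are counted as enlarged by
#' [clip_predictions()].
#'
#' @param model a `lur_model`.
#' @param ppv_rasters named list of `raster_grid`s covering every model term.
#' @return a `raster_grid` of predicted concentrations in ppb.
#' @export
predict_surface <- function(model, ppv_rasters) {
  vars <- model$terms$name
  missing_terms <- setdiff(vars, names(ppv_rasters))
  if (length(missing_terms))
    stop("no raster supplied for model term: ",
         paste(missing_terms, collapse = ", "))
  template <- if (length(vars)) ppv_rasters[[vars[1]]] else ppv_rasters[[1]]
  acc <- matrix(model$intercept, nrow(template$values), ncol(template$values))
  for (i in seq_along(vars)) {
    g <- nodata_to_zero(ppv_rasters[[vars[i]]])
    x <- g$values
    tr <- model$ppv_transforms[[vars[i]]]
    if (!is.null(tr) && tr$tag != "identity")
      x <- ppv_transform_fun(tr$tag, tr$eps)(x)
    acc <- acc + model$terms$coef[i] * x
  }
  pred <- transform_invert(model$transform, acc)
  raster_grid(matrix(pred, nrow(acc), ncol(acc)), template$cell_size,
              template$origin)
}

#' Apply floor and ceiling rules to a predicted surface
#'
#' The limit of prediction for low values is the minimum observed
#' concentration divided by sqrt(2); cells below it (and cells whose
#' back-transform was undefined) are raised to it. Cells above 120% of the
#' maximum observed concentration are truncated to that ceiling. The
#' reported fractions refer to the pre-clip distribution.
#'
#' @param raster predicted `raster_grid` (ppb).
#' @param observed_min,observed_max minimum and maximum observed
#'   concentrations (ppb) for the matching pollutant and period.
#' @return an object of class `map_result`: the clipped raster plus floor,
#'   ceiling, cell counts and affected fractions.
#' @export
clip_predictions <- function(raster, observed_min, observed_max) {
  if (observed_min <= 0) stop("observed_min must be positive")
  if (observed_max <= observed_min)
    stop("observed_max must exceed observed_min")
  floor_v <- observed_min / sqrt(2)
  ceil_v <- 1.2 * observed_max
  if (floor_v >= ceil_v) stop("floor >= ceiling: pathological inputs")
  v <- raster$values
  n <- length(v)
  enlarged <- is.na(v) | v < floor_v
  truncated <- !is.na(v) & v > ceil_v
  v[enlarged] <- floor_v
  v[truncated] <- ceil_v
  structure(list(
    raster = raster_grid(v, raster$cell_size, raster$origin),
    floor = floor_v, ceiling = ceil_v,
    n_cells = n, n_enlarged = sum(enlarged), n_truncated = sum(truncated),
    frac_enlarged = sum(enlarged) / n,
    frac_truncated = sum(truncated) / n),
    class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("<map_result> %d cells; floor %.1f ppb, ceiling %.1f ppb\n",
              x$n_cells, x$floor, x$ceiling))
  cat(sprintf("  enlarged to floor: %.1f%%; truncated to ceiling: %.1f%%\n",
              100 * x$frac_enlarged, 100 * x$frac_truncated))
  invisible(x)
}

#' Clip-report summary across models
#'
#' @param map_results named list of `map_result`s.
#' @return data.frame: model, floor, ceiling, pct_enlarged, pct_truncated
#'   (percentages at 0.1 resolution).
#' @export
clip_report <- function(map_results) {
  data.frame(
    model = names(map_results),
    floor_ppb = vapply(map_results, `[[`, numeric(1), "floor"),
    ceiling_ppb = vapply(map_results, `[[`, numeric(1), "ceiling"),
    pct_enlarged = round(100 * vapply(map_results, `[[`, numeric(1),
                                      "frac_enlarged"), 1),
    pct_truncated = round(100 * vapply(map_results, `[[`, numeric(1),
                                       "frac_truncated"), 1),
    row.names = NULL, stringsAsFactors = FALSE)
}
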