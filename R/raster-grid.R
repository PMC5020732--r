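#' Planar raster grid
#'
#' A minimal raster container: a numeric matrix of cell values with a
#' top-left outer-corner origin and a square cell size, both in metres.
#' Rows increase southward (row 1 is the northern edge), columns increase
#' eastward. Nodata cells are stored as `NA`. Cell centres sit at
#' `origin + (index - 0.5) * cell_size`, and all extents are half-open
#' (a point on the right or bottom edge is outside the grid).
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, (x, y) of the top-left outer corner.
#'   Defaults so the grid spans `[0, ncol * cell_size) x (0, nrow * cell_size]`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size,
                        origin = c(0, nrow(values) * cell_size)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be numeric length 2")
  if (any(!is.finite(values) & !is.na(values)))
    stop("raster values must be finite or NA (nodata)")
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell_size %g m\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (top-left): (%g, %g)\n", x$origin[1], x$origin[2]))
  cat(sprintf("  nodata cells: %d; value range: [%g, %g]\n",
              sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Blank raster covering a rectangular extent
#'
#' @param extent numeric length 4: (xmin, xmax, ymin, ymax) in metres.
#' @param cell_size cell edge length in metres.
#' @param value fill value, default 0.
#' @return a `raster_grid` whose top-left origin is (xmin, ymax).
#' @export
grid_template <- function(extent, cell_size, value = 0) {
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("`extent` must be (xmin, xmax, ymin, ymax) with positive spans")
  nc <- ceiling((extent[2] - extent[1]) / cell_size - 1e-9)
  nr <- ceiling((extent[4] - extent[3]) / cell_size - 1e-9)
  raster_grid(matrix(value, nr, nc), cell_size,
              origin = c(extent[1], extent[4]))
}

#' Grid extent (xmin, xmax, ymin, ymax)
#' @param g a `raster_grid`.
#' @export
grid_extent <- function(g) {
  c(g$origin[1], g$origin[1] + ncol(g$values) * g$cell_size,
    g$origin[2] - nrow(g$values) * g$cell_size, g$origin[2])
}

#' Cell-centre coordinates
#' @param g a `raster_grid`.
#' @return list with `x` (length ncol) and `y` (length nrow, north to south).
#' @export
cell_centers <- function(g) {
  cs <- g$cell_size
  list(x = g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * cs,
       y = g$origin[2] - (seq_len(nrow(g$values)) - 0.5) * cs)
}

#' Map points to cell indices
#'
#' @param g a `raster_grid`.
#' @param x,y point coordinates in metres.
#' @return data.frame with columns `row`, `col` (`NA` outside the grid).
#' @export
point_to_cell <- function(g, x, y) {
  cs <- g$cell_size
  col <- floor((x - g$origin[1]) / cs) + 1L
  row <- floor((g$origin[2] - y) / cs) + 1L
  # the northern edge is inclusive (half-open southward)
  row[y == g$origin[2]] <- 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' Returns the value of the cell containing each point, without
#' interpolation (the grid-cell-under-the-station convention).
#'
#' @param g a `raster_grid`.
#' @param x,y point coordinates.
#' @return numeric vector; `NA` for points outside the grid or nodata cells.
#' @export
extract_values <- function(g, x, y) {
  idx <- point_to_cell(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- g$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Replace nodata cells with zero
#'
#' Mirrors the GIS convention used before regression mapping: cells outside
#' any buffer come back as null and are set to zero so every predictor is
#' defined everywhere.
#'
#' @param g a `raster_grid`.
#' @return the same grid with `NA` cells set to 0.
#' @export
nodata_to_zero <- function(g) {
  v <- g$values
  v[is.na(v)] <- 0
  raster_grid(v, g$cell_size, g$origin)
}

#' Nearest-neighbour resample onto a template grid
#' @param g source `raster_grid`.
#' @param template target `raster_grid` (its values are ignored).
#' @export
resample_nearest <- function(g, template) {
  cc <- cell_centers(template)
  xy <- expand.grid(y = cc$y, x = cc$x) # column-major over template values
  vals <- extract_values(g, xy$x, xy$y)
  raster_grid(matrix(vals, nrow(template$values), ncol(template$values)),
              template$cell_size, template$origin)
}

#' Write a raster as an ESRI ASCII grid
#' @param g a `raster_grid`.
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - nrow(v) * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  v[is.na(v)] <- nodata
  utils::write.table(format(v, trim = TRUE, digits = 10, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return a `raster_grid`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  n_hdr <- sum(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                          "cellsize", "nodata_value"))
  m <- as.matrix(utils::read.table(path, skip = n_hdr))
  dimnames(m) <- NULL
  if (!is.na(val["nodata_value"])) m[m == val["nodata_value"]] <- NA
  raster_grid(m, val[["cellsize"]],
              origin = c(val[["xllcorner"]],
                         val[["yllcorner"]] + nrow(m) * val[["cellsize"]]))
}
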