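# Spatial primitives: rasterization, circular focal sums, exact Euclidean
# distance transforms, kernel density and slope. These reproduce, on a
# planar grid, what the GIS neighborhood/distance/density tools do when
# turning vector inputs into buffer-type predictor surfaces.

# -- rasterization -----------------------------------------------------------

point_in_ring <- function(px, py, ring) {
  # even-odd ray casting, vectorized over points
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

point_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) inside <- xor(inside, point_in_ring(px, py, r))
  inside
}

# sample a polyline at subsegment midpoints so that only cells whose
# intersection with the line has positive length are touched
line_samples <- function(coords, step) {
  out <- vector("list", nrow(coords) - 1L)
  for (s in seq_len(nrow(coords) - 1L)) {
    p0 <- coords[s, ]; p1 <- coords[s + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    k <- max(1L, ceiling(len / step))
    t <- (seq_len(k) - 0.5) / k
    out[[s]] <- cbind(p0[1] + t * (p1[1] - p0[1]),
                      p0[2] + t * (p1[2] - p0[2]),
                      len / k)
  }
  do.call(rbind, out)
}

#' Rasterize a vector layer
#'
#' Burns features onto a template grid. In `presence` mode a cell gets 1 if
#' it contains a point, if a polyline crosses it with positive length, or if
#' its centre lies inside a polygon; 0 otherwise. `length_weight` accumulates
#' the (approximate) line length per cell in metres; `area_weight` the
#' covered cell fraction, estimated on a 4 x 4 subsample per cell.
#'
#' @param layer a `vector_layer`.
#' @param template a `raster_grid` defining extent and resolution.
#' @param mode one of `"presence"`, `"length_weight"`, `"area_weight"`.
#' @return a `raster_grid`; an empty layer yields an all-zero raster with a
#'   warning (distance operations guard against this explicitly).
#' @export
rasterize <- function(layer, template,
                      mode = c("presence", "length_weight", "area_weight")) {
  mode <- match.arg(mode)
  if (template$cell_size <= 0) stop("template cell_size must be positive")
  v <- matrix(0, nrow(template$values), ncol(template$values))
  out <- raster_grid(v, template$cell_size, template$origin)
  if (length(layer) == 0L) {
    warning("rasterize: empty layer, returning all-zero raster")
    return(out)
  }
  cs <- template$cell_size
  acc <- v
  for (f in layer$features) {
    g <- f$geometry
    if (g$type == "point") {
      idx <- point_to_cell(out, g$coords[1], g$coords[2])
      if (!is.na(idx$row))
        acc[idx$row, idx$col] <- if (mode == "presence") 1 else
          acc[idx$row, idx$col] + 1
    } else if (g$type == "polyline") {
      sm <- line_samples(g$coords, step = cs / 4)
      if (is.null(sm)) next
      idx <- point_to_cell(out, sm[, 1], sm[, 2])
      ok <- !is.na(idx$row)
      if (!any(ok)) next
      if (mode == "length_weight") {
        key <- (idx$col[ok] - 1L) * nrow(acc) + idx$row[ok]
        tab <- tapply(sm[ok, 3], key, sum)
        acc[as.integer(names(tab))] <- acc[as.integer(names(tab))] + tab
      } else {
        acc[cbind(idx$row[ok], idx$col[ok])] <- 1
      }
    } else { # polygon
      rings <- g$coords
      bb <- apply(do.call(rbind, rings), 2, range)
      cc <- cell_centers(out)
      ci <- which(cc$x >= bb[1, 1] - cs & cc$x <= bb[2, 1] + cs)
      ri <- which(cc$y >= bb[1, 2] - cs & cc$y <= bb[2, 2] + cs)
      if (!length(ci) || !length(ri)) next
      if (mode == "area_weight") {
        # 4 x 4 subsample within each candidate cell
        offs <- (seq_len(4) - 0.5) / 4
        frac <- matrix(0, length(ri), length(ci))
        for (oy in offs) for (ox in offs) {
          px <- rep(out$origin[1] + (ci - 1 + ox) * cs, each = length(ri))
          py <- rep(out$origin[2] - (ri - 1 + oy) * cs, times = length(ci))
          frac <- frac + matrix(point_in_polygon(px, py, rings),
                                length(ri), length(ci)) / 16
        }
        acc[ri, ci] <- acc[ri, ci] + frac
      } else {
        px <- rep(cc$x[ci], each = length(ri))
        py <- rep(cc$y[ri], times = length(ci))
        ins <- matrix(point_in_polygon(px, py, rings), length(ri), length(ci))
        block <- acc[ri, ci, drop = FALSE]
        block[ins] <- 1
        acc[ri, ci] <- block
      }
    }
  }
  raster_grid(acc, cs, template$origin)
}

# -- focal sum ---------------------------------------------------------------

next_fast_size <- function(n) {
  # smallest 5-smooth integer >= n, for efficient mixed-radix FFTs
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

conv2d_same <- function(A, K) {
  m <- nrow(A); n <- ncol(A); km <- nrow(K); kn <- ncol(K)
  M <- next_fast_size(m + km - 1L); N <- next_fast_size(n + kn - 1L)
  PA <- matrix(0, M, N); PA[seq_len(m), seq_len(n)] <- A
  PK <- matrix(0, M, N); PK[seq_len(km), seq_len(kn)] <- K
  full <- Re(stats::fft(stats::fft(PA) * stats::fft(PK), inverse = TRUE)) /
    (M * N)
  rc <- (km - 1L) %/% 2L; cc <- (kn - 1L) %/% 2L
  full[rc + seq_len(m), cc + seq_len(n), drop = FALSE]
}

disc_kernel <- function(radius, cell_size) {
  r_cells <- floor(radius / cell_size + 1e-9)
  off <- (-r_cells):r_cells
  d2 <- outer(off^2, off^2, "+") * cell_size^2
  (d2 <= radius^2 + 1e-6) * 1
}

#' Circular focal sum
#'
#' Each output cell is the sum of input values over all cells whose centre
#' lies within Euclidean distance `radius` of the output cell's centre
#' (centre-to-centre, the circular-neighborhood focal statistic). Edge cells
#' sum over the in-grid part only; nodata cells contribute zero.
#'
#' @param raster a `raster_grid`.
#' @param radius neighborhood radius in metres; must be at least one cell.
#' @return a `raster_grid` of neighborhood sums.
#' @export
focal_sum <- function(raster, radius) {
  if (radius < raster$cell_size)
    stop("focal_sum radius must be >= cell_size")
  A <- raster$values
  A[is.na(A)] <- 0
  K <- disc_kernel(radius, raster$cell_size)
  out <- conv2d_same(A, K)
  # FFT round-off can leave tiny negatives on zero cells
  out[abs(out) < 1e-9] <- 0
  raster_grid(out, raster$cell_size, raster$origin)
}

# -- Euclidean distance transform -------------------------------------------

BIG_DT <- 1e20

dt1d <- function(f) {
  # exact 1-D squared distance transform (lower envelope of parabolas)
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  if (n > 1L) for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest feature cell
#'
#' Exact centre-to-centre distance transform: each cell's value is the
#' distance in metres from its centre to the nearest cell centre with a
#' positive (feature) value in the input presence raster. Feature cells
#' get 0.
#'
#' @param features a `raster_grid` presence raster (positive = feature).
#' @return a `raster_grid` of distances in metres.
#' @export
euclidean_distance <- function(features) {
  A <- features$values
  feat <- !is.na(A) & A > 0
  if (!any(feat)) stop("euclidean_distance: no feature cells")
  F0 <- matrix(BIG_DT, nrow(A), ncol(A))
  F0[feat] <- 0
  # columns then rows
  D <- apply(F0, 2, dt1d)
  D <- t(apply(D, 1, dt1d))
  raster_grid(features$cell_size * sqrt(D), features$cell_size,
              features$origin)
}

#' Natural log of distance with a one-cell offset
#'
#' Computes `log(d + eps)` with `eps` defaulting to one cell size, so that
#' feature cells (d = 0) map to `log(cell_size)` instead of -Inf. Preserves
#' the ordering of distances.
#'
#' @param dist a `raster_grid` of nonnegative distances (metres).
#' @param eps offset in metres; default one cell size.
#' @return a `raster_grid`.
#' @export
log_distance <- function(dist, eps = dist$cell_size) {
  v <- dist$values
  if (any(v < 0, na.rm = TRUE)) stop("log_distance: negative distances")
  raster_grid(log(v + eps), dist$cell_size, dist$origin)
}

# -- kernel density ----------------------------------------------------------

#' Kernel density of weighted points
#'
#' Quartic (Epanechnikov-type) kernel density surface: each point of weight
#' w contributes w * (3 / (pi r^2)) * (1 - (d/r)^2)^2 within distance r and
#' zero beyond, so its mass integrates to w. Output units are per square
#' kilometre (persons per km^2 for population weights).
#'
#' @param points a `vector_layer` of point features, or a matrix/data.frame
#'   with columns x, y.
#' @param weights numeric weights (>= 0); for a `vector_layer`, defaults to
#'   the `weight` attribute.
#' @param radius kernel radius (bandwidth) in metres, > 0.
#' @param template a `raster_grid` defining the output grid.
#' @return a `raster_grid` of densities per km^2.
#' @export
kernel_density <- function(points, radius, template, weights = NULL) {
  if (radius <= 0) stop("kernel_density: radius must be positive")
  if (inherits(points, "vector_layer")) {
    xy <- vl_coords(points)
    if (is.null(weights)) weights <- as.numeric(vl_attr(points, "weight"))
  } else {
    xy <- as.matrix(points)[, 1:2, drop = FALSE]
  }
  if (is.null(weights)) stop("kernel_density: weights required")
  if (any(is.na(weights)) || any(weights < 0))
    stop("kernel_density: weights must be >= 0")
  cs <- template$cell_size
  cc <- cell_centers(template)
  acc <- matrix(0, nrow(template$values), ncol(template$values))
  norm <- 3 / (pi * radius^2)
  for (i in seq_len(nrow(xy))) {
    w <- weights[i]
    if (w == 0) next
    ci <- which(abs(cc$x - xy[i, 1]) <= radius)
    ri <- which(abs(cc$y - xy[i, 2]) <= radius)
    if (!length(ci) || !length(ri)) next
    d2 <- outer((cc$y[ri] - xy[i, 2])^2, (cc$x[ci] - xy[i, 1])^2, "+")
    k <- (1 - d2 / radius^2)^2
    k[d2 > radius^2] <- 0
    acc[ri, ci] <- acc[ri, ci] + w * norm * k
  }
  raster_grid(acc * 1e6, cs, template$origin) # per m^2 -> per km^2
}

# -- slope -------------------------------------------------------------------

#' Slope in degrees from a DEM (Horn's method)
#'
#' 3 x 3 finite-difference gradient with the Horn weighting; the border is
#' handled by replicating edge cells, so only interior cells carry the exact
#' stencil. A flat DEM yields zero everywhere.
#'
#' @param dem a `raster_grid` of elevations in metres, at least 3 x 3.
#' @return a `raster_grid` of slopes in degrees.
#' @export
slope_from_dem <- function(dem) {
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop("slope_from_dem: grid must be >= 3x3")
  cs <- dem$cell_size
  nr <- nrow(z); nc <- ncol(z)
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)] # replicate borders
  idx <- function(di, dj) zp[di + seq_len(nr), dj + seq_len(nc)]
  # neighbours: a b c / d e f / g h i (row-down, col-right)
  a <- idx(0, 0); b <- idx(0, 1); cq <- idx(0, 2)
  d <- idx(1, 0);                 f <- idx(1, 2)
  g <- idx(2, 0); h <- idx(2, 1); i9 <- idx(2, 2)
  dzdx <- ((cq + 2 * f + i9) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i9) - (a + 2 * b + cq)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  raster_grid(slope, cs, dem$origin)
}
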