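# Synthetic city with known ground truth. The generator lays roads on a
# jittered grid, grows land-use regions on a block lattice (which induces
# realistic spatial correlation between predictors), scatters facilities,
# and builds a smooth DEM, so that every buffer/distance/density predictor
# class is computable and a log-linear concentration surface with known
# coefficients can be simulated at monitoring stations.

LANDUSE_TYPES <- c("RES", "GRS", "URF", "IND", "OFIC", "TRS", "SNS",
                   "AGR", "ARD", "OTHR")

FACILITY_KINDS <- c("primary_school", "high_school", "petrol_station",
                    "bus_terminal", "airport", "hazardous_facility",
                    "mosque", "park", "food_shop", "ambulance", "sport_land")

#' City generator configuration
#'
#' Defaults describe a 3 km x 3 km city rasterized at 20 m: large enough to
#' carry multi-hundred-metre buffers and kernel radii, small enough for
#' desk-scale runs. All lengths in metres.
#'
#' @param extent side length of the square city, >= 1000 (area >= 1 km^2).
#' @param cell_size raster resolution for the DEM and derived predictors.
#' @param block_size land-use block lattice pitch.
#' @param road_spacing nominal spacing of the jittered road grid.
#' @param road_jitter maximum perpendicular jitter of road positions.
#' @param n_bridges number of bridge segments on major roads.
#' @param taczone_radius radius of the central traffic access control zone.
#' @param facilities_per_kind named integer vector of point counts.
#' @param landuse_weights named sampling weights for the 10 land-use types.
#' @param pop_per_km2 nominal residential population density.
#' @param tpdc_frac fraction of the population that is employed or over
#'   five years of age (the adjusted population weight).
#' @param dem_base,dem_relief,dem_bump_amp DEM: base elevation, south-north
#'   relief, and amplitude of random hills (m).
#' @return a validated config list of class `city_config`.
#' @export
city_config <- function(extent = 3000, cell_size = 20, block_size = 200,
                        road_spacing = 300, road_jitter = 40, n_bridges = 12,
                        taczone_radius = 450,
                        facilities_per_kind = c(
                          primary_school = 20, high_school = 12,
                          petrol_station = 10, bus_terminal = 6, airport = 1,
                          hazardous_facility = 5, mosque = 15, park = 12,
                          food_shop = 25, ambulance = 8, sport_land = 8),
                        landuse_weights = c(
                          RES = 0.30, GRS = 0.12, URF = 0.08, IND = 0.08,
                          OFIC = 0.10, TRS = 0.08, SNS = 0.04, AGR = 0.06,
                          ARD = 0.08, OTHR = 0.06),
                        pop_per_km2 = 12000, tpdc_frac = 0.65,
                        dem_base = 1100, dem_relief = 500, dem_bump_amp = 40) {
  if (extent^2 < 1e6) stop("city extent area must be >= 1 km^2")
  if (taczone_radius <= 0) stop("taczone_radius must be positive")
  if (road_spacing <= 0 || road_spacing >= extent)
    stop("road_spacing must be in (0, extent): the road grid would be empty")
  if (!setequal(names(landuse_weights), LANDUSE_TYPES) ||
      any(landuse_weights <= 0))
    stop("landuse_weights must name all 10 land-use types with positive weight")
  if (!all(FACILITY_KINDS %in% names(facilities_per_kind)) ||
      any(facilities_per_kind < 1))
    stop("facilities_per_kind must cover all facility kinds with counts >= 1")
  structure(as.list(environment()), class = "city_config")
}

grow_landuse <- function(nb, weights, n_extra_seeds) {
  # seeded region growing on an nb x nb block lattice; one guaranteed seed
  # per type, then weighted extras, then random-frontier BFS fill
  lab <- matrix(NA_integer_, nb, nb)
  types <- seq_along(LANDUSE_TYPES)
  n_seed <- length(types) + n_extra_seeds
  pos <- sample.int(nb * nb, n_seed)
  lab[pos[types]] <- types
  if (n_extra_seeds > 0)
    lab[pos[-types]] <- sample(types, n_extra_seeds, replace = TRUE,
                               prob = weights[LANDUSE_TYPES])
  while (anyNA(lab)) {
    empty <- which(is.na(lab))
    er <- (empty - 1L) %% nb + 1L
    ec <- (empty - 1L) %/% nb + 1L
    # neighbours of empty cells that are labelled
    cand_lab <- rep(NA_integer_, length(empty))
    ord <- sample(length(empty))
    filled_any <- FALSE
    for (k in ord) {
      r <- er[k]; c <- ec[k]
      nbr <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      nbr <- nbr[nbr[, 1] >= 1 & nbr[, 1] <= nb &
                 nbr[, 2] >= 1 & nbr[, 2] <= nb, , drop = FALSE]
      labs <- lab[nbr]
      labs <- labs[!is.na(labs)]
      if (length(labs)) {
        lab[r, c] <- labs[sample.int(length(labs), 1L)]
        filled_any <- TRUE
      }
    }
    if (!filled_any) break # isolated region: cannot happen on a 4-lattice
  }
  lab
}

#' Generate a synthetic city scene
#'
#' Deterministic given `(config, seed)`. The scene contains every input
#' layer kind needed by the predictor catalog: roads in three classes
#' (streets, major roads, highways), bridges, ten land-use polygon types,
#' eleven facility point kinds, a central traffic access control zone (plus
#' its enlarged critical-episode variant), weighted population centroids,
#' and a DEM.
#'
#' @param config a [city_config()].
#' @param seed integer RNG seed.
#' @return an object of class `city_scene`.
#' @export
generate_city <- function(config = city_config(), seed = 1L) {
  if (!inherits(config, "city_config")) stop("config must be a city_config")
  set.seed(seed)
  ext <- config$extent

  # roads: jittered grid of straight lines; middle lines are highways,
  # every third remaining line a major road, the rest streets
  base_pos <- seq(config$road_spacing / 2, ext - config$road_spacing / 4,
                  by = config$road_spacing)
  classify <- function(n) {
    cls <- rep("street", n)
    cls[seq(2, n, by = 3)] <- "major_road"
    cls[ceiling(n / 2)] <- "highway"
    cls
  }
  road_feats <- list()
  for (orient in c("v", "h")) {
    pos <- pmin(pmax(base_pos +
      stats::runif(length(base_pos), -config$road_jitter, config$road_jitter),
      config$cell_size), ext - config$cell_size)
    cls <- classify(length(pos))
    for (i in seq_along(pos)) {
      coords <- if (orient == "v") cbind(c(pos[i], pos[i]), c(0, ext))
                else cbind(c(0, ext), c(pos[i], pos[i]))
      road_feats <- c(road_feats, vl_line(coords, class = cls[i]))
    }
  }
  roads <- vector_layer(road_feats)
  major <- vl_subset(roads, "class", c("major_road", "highway"))

  # bridges: short segments at random positions along major roads
  bridge_feats <- list()
  mcoords <- lapply(major$features, function(f) f$geometry$coords)
  for (b in seq_len(config$n_bridges)) {
    rd <- mcoords[[sample.int(length(mcoords), 1L)]]
    t0 <- stats::runif(1, 0.1, 0.9)
    len <- stats::runif(1, 80, 150)
    dirv <- rd[2, ] - rd[1, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    mid <- rd[1, ] + t0 * (rd[2, ] - rd[1, ])
    p0 <- mid - dirv * len / 2
    p1 <- mid + dirv * len / 2
    bridge_feats <- c(bridge_feats, vl_line(rbind(p0, p1), kind = "bridge"))
  }
  bridges <- vector_layer(bridge_feats)

  # land use: region-grown block lattice, one square polygon per block
  nb <- max(4L, round(ext / config$block_size))
  bs <- ext / nb
  lab <- grow_landuse(nb, config$landuse_weights,
                      n_extra_seeds = max(0L, round(nb * nb / 10)))
  lu_feats <- list()
  for (r in seq_len(nb)) for (c in seq_len(nb)) {
    lu_feats <- c(lu_feats, vl_rect((c - 1) * bs, c * bs,
                                    ext - r * bs, ext - (r - 1) * bs,
                                    type = LANDUSE_TYPES[lab[r, c]]))
  }
  landuse <- vector_layer(lu_feats)

  # traffic access control zone: central 16-gon, plus the enlarged zone
  # used under critical air pollution episodes
  centre <- ext / 2 + stats::runif(2, -ext / 20, ext / 20)
  ngon <- function(centre, radius, n = 16, irregular = 0) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    r <- radius * (1 + stats::runif(n, -irregular, irregular))
    cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
  }
  # the critical-episode zone is a larger, irregular district containing
  # the core zone, not a concentric copy of it
  tacap_r <- 2.5 * config$taczone_radius
  off_ang <- stats::runif(1, 0, 2 * pi)
  off_len <- stats::runif(1, 0, 0.6 * (tacap_r - config$taczone_radius))
  tacap_c <- centre + off_len * c(cos(off_ang), sin(off_ang))
  taczone <- vector_layer(c(
    vl_polygon(ngon(centre, config$taczone_radius), kind = "TACZ"),
    vl_polygon(ngon(tacap_c, tacap_r, irregular = 0.25), kind = "TACAP")))

  # facilities: mixture of near-road and uniform placements
  road_pts <- do.call(rbind, lapply(roads$features, function(f) {
    cc <- f$geometry$coords
    t <- stats::runif(8)
    cbind(cc[1, 1] + t * (cc[2, 1] - cc[1, 1]),
          cc[1, 2] + t * (cc[2, 2] - cc[1, 2]))
  }))
  fac_feats <- list()
  for (kind in FACILITY_KINDS) {
    n <- config$facilities_per_kind[[kind]]
    near_road <- stats::runif(n) < 0.5
    pts <- matrix(0, n, 2)
    k_near <- sum(near_road)
    if (k_near > 0) {
      base <- road_pts[sample.int(nrow(road_pts), k_near, replace = TRUE), ,
                       drop = FALSE]
      pts[near_road, ] <- base + matrix(stats::rnorm(2 * k_near, 0, 60),
                                        k_near, 2)
    }
    if (any(!near_road))
      pts[!near_road, ] <- matrix(stats::runif(2 * sum(!near_road), 0, ext),
                                  sum(!near_road), 2)
    pts <- pmin(pmax(pts, config$cell_size / 2), ext - config$cell_size / 2)
    fac_feats <- c(fac_feats, vl_points(pts, kind = kind))
  }
  facilities <- vector_layer(fac_feats)

  # population: jittered block centroids, weight proportional to land-use
  # dependent density; adjusted weight excludes unemployed and under-fives
  dens_factor <- c(RES = 1, GRS = 0.02, URF = 0.35, IND = 0.10, OFIC = 0.40,
                   TRS = 0.05, SNS = 0.05, AGR = 0.05, ARD = 0.01,
                   OTHR = 0.20)
  pop_feats <- list()
  for (r in seq_len(nb)) for (c in seq_len(nb)) {
    type <- LANDUSE_TYPES[lab[r, c]]
    w <- config$pop_per_km2 * dens_factor[[type]] * (bs / 1000)^2 *
      stats::runif(1, 0.6, 1.4)
    cx <- (c - 0.5) * bs + stats::runif(1, -bs / 4, bs / 4)
    cy <- ext - (r - 0.5) * bs + stats::runif(1, -bs / 4, bs / 4)
    w_adj <- w * min(1, max(0, config$tpdc_frac + stats::runif(1, -0.05, 0.05)))
    pop_feats <- c(pop_feats, vl_points(cbind(cx, cy), weight = w,
                                        weight_adj = w_adj))
  }
  population <- vector_layer(pop_feats)

  # DEM: south-north ramp plus random smooth hills
  template <- grid_template(c(0, ext, 0, ext), config$cell_size)
  cc <- cell_centers(template)
  z <- matrix(config$dem_base, length(cc$y), length(cc$x))
  z <- z + config$dem_relief *
    matrix(rep(cc$y / ext, times = length(cc$x)), length(cc$y))
  for (h in seq_len(6)) {
    hx <- stats::runif(1, 0, ext); hy <- stats::runif(1, 0, ext)
    amp <- stats::runif(1, -1, 1) * config$dem_bump_amp
    sig <- stats::runif(1, ext / 10, ext / 4)
    d2 <- outer((cc$y - hy)^2, (cc$x - hx)^2, "+")
    z <- z + amp * exp(-d2 / (2 * sig^2))
  }
  dem <- raster_grid(z, config$cell_size, template$origin)

  structure(list(extent = c(0, ext, 0, ext), cell_size = config$cell_size,
                 roads = roads, bridges = bridges, landuse = landuse,
                 facilities = facilities, taczone = taczone,
                 population = population, dem = dem,
                 config = config, seed = seed),
            class = "city_scene")
}

#' @export
print.city_scene <- function(x, ...) {
  cat(sprintf("<city_scene> %g x %g m at %g m cells (seed %d)\n",
              x$extent[2], x$extent[4], x$cell_size, x$seed))
  cat(sprintf("  roads: %d, bridges: %d, land-use polygons: %d, facilities: %d\n",
              length(x$roads), length(x$bridges), length(x$landuse),
              length(x$facilities)))
  invisible(x)
}

#' Place monitoring stations uniformly in a scene
#'
#' @param scene a `city_scene`.
#' @param n number of stations.
#' @param seed integer RNG seed.
#' @param border margin kept from the city edge, metres.
#' @return data.frame with columns station_id, x, y.
#' @export
place_stations <- function(scene, n, seed = 1L, border = NULL) {
  set.seed(seed)
  if (is.null(border)) border <- scene$cell_size
  ext <- scene$extent
  data.frame(station_id = sprintf("ST%02d", seq_len(n)),
             x = stats::runif(n, ext[1] + border, ext[2] - border),
             y = stats::runif(n, ext[3] + border, ext[4] - border),
             stringsAsFactors = FALSE)
}
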