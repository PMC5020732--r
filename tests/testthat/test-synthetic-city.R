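test_that("city generation is deterministic and structurally complete", {
  s1 <- generate_city(tiny_config(), seed = 7)
  s2 <- generate_city(tiny_config(), seed = 7)
  expect_identical(s1$roads, s2$roads)
  expect_identical(s1$landuse, s2$landuse)
  expect_identical(s1$dem$values, s2$dem$values)
  # all 10 land-use types, all facility kinds, road classes present
  expect_setequal(unique(vl_attr(s1$landuse, "type")),
                  c("RES", "GRS", "URF", "IND", "OFIC", "TRS", "SNS",
                    "AGR", "ARD", "OTHR"))
  expect_length(unique(vl_attr(s1$roads, "class")), 3)
  # facilities inside the extent, population weights nonnegative
  fxy <- vl_coords(vl_subset(s1$facilities, "kind",
                             unique(vl_attr(s1$facilities, "kind"))))
  expect_true(all(fxy >= 0 & fxy <= 1500))
  expect_true(all(as.numeric(vl_attr(s1$population, "weight")) >= 0))
})

test_that("degenerate generator configs are rejected", {
  expect_error(city_config(taczone_radius = 0), "taczone_radius")
  expect_error(city_config(road_spacing = 2000, extent = 1500), "road grid")
  expect_error(city_config(extent = 800), "1 km")
})

test_that("noise-free simulation matches the closed-form log-linear truth", {
  scene <- tiny_scene()
  st <- place_stations(scene, 5, seed = 3)
  truth <- quiet_truth(c("LNDIST.PRSC" = 0.3), base_level = 25)
  ser <- simulate_concentrations(scene, st, truth, seed = 1)
  x <- compute_ppv("LNDIST.PRSC", scene)
  xs <- extract_values(x, st$x, st$y)
  ann <- tapply(ser$no, ser$station_id, mean)[st$station_id]
  expect_equal(as.numeric(ann), 25 * exp(0.3 * xs), tolerance = 1e-10)
  # NOx is NO + NO2 at every hour, noise or not
  noisy <- simulate_concentrations(scene, st, default_truth(), seed = 2)
  expect_equal(noisy$nox, noisy$no + noisy$no2)
  expect_true(all(noisy$nox >= pmax(noisy$no, noisy$no2)))
})

test_that("seasonal multipliers raise cooler-season means at every station", {
  scene <- tiny_scene()
  st <- place_stations(scene, 10, seed = 4)
  # doubling all (positive-contribution) coefficients in the cooler season
  tr <- ground_truth(active = c("LNDIST.PRSC" = 0.3),
                     seasonal_shift = list(cooler = 2, warmer = 1),
                     noise_sd = 0.1, shared_sd = 0, diurnal_amp = 0,
                     base_level = 20)
  ser <- simulate_concentrations(scene, st, tr, seed = 5)
  season <- ifelse(as.integer(format(ser$timestamp, "%m")) %in% 4:9,
                   "warmer", "cooler")
  cool <- tapply(ser$no[season == "cooler"],
                 ser$station_id[season == "cooler"], mean)
  warm <- tapply(ser$no[season == "warmer"],
                 ser$station_id[season == "warmer"], mean)
  expect_true(all(cool > warm))
  # station outside the extent is refused by id
  bad <- rbind(st, data.frame(station_id = "OUT", x = 99999, y = 10))
  expect_error(simulate_concentrations(scene, bad, tr, seed = 1), "OUT")
})

test_that("missingness mechanisms hit the requested rate deterministically", {
  scene <- tiny_scene()
  st <- place_stations(scene, 2, seed = 6)
  ser <- simulate_concentrations(scene, st, quiet_truth(c("SLP" = 0.01)),
                                 seed = 7)
  expect_identical(apply_missingness(ser, 0, seed = 1), ser)
  m <- apply_missingness(ser, 0.281, "mcar", seed = 8)
  for (sid in st$station_id) {
    k <- sum(is.na(m$no[m$station_id == sid]))
    expect_gte(k, 2377)  # 28% +/- 1% of 8760
    expect_lte(k, 2529)
  }
  expect_identical(apply_missingness(ser, 0.281, "mcar", seed = 8), m)
  # block mechanism produces contiguous gaps
  b <- apply_missingness(ser, 0.28, "block", seed = 9)
  gap_runs <- rle(is.na(b$no[b$station_id == st$station_id[1]]))
  expect_gt(max(gap_runs$lengths[gap_runs$values]), 24)
  expect_error(apply_missingness(ser, 1.0), "rate")
})

test_that("hourly CSV round-trips values, timestamps and gaps", {
  scene <- tiny_scene()
  st <- place_stations(scene, 2, seed = 10)
  ser <- simulate_concentrations(scene, st, default_truth(), seed = 11)
  ser <- apply_missingness(ser, 0.1, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hourly_csv(ser, path)
  back <- read_hourly_csv(path)
  expect_equal(back$timestamp, ser$timestamp)
  expect_equal(back$no, ser$no, tolerance = 1e-9)
  expect_equal(is.na(back$no2), is.na(ser$no2))
})
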