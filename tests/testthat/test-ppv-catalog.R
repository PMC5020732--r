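test_that("the catalog reproduces the full 210-variable inventory", {
  catal <- build_catalog()
  counts <- attr(catal, "class_counts")
  expect_equal(unname(counts[c("traffic", "landuse", "distance",
                               "population", "product", "geographic")]),
               c(26, 50, 58, 22, 52, 2), ignore_attr = TRUE)
  expect_equal(nrow(catal), 210)
  expect_identical(build_catalog(), catal) # construction is pure
})

test_that("sign priors match the a-priori effect directions", {
  catal <- build_catalog()
  prior <- stats::setNames(catal$sign_prior, catal$name)
  expect_equal(unname(prior["GRS.500"]), "-")
  expect_equal(unname(prior["SLP"]), "none")
  expect_equal(unname(prior["ELEV"]), "none")
  expect_equal(unname(prior["ST.100"]), "+")
  expect_equal(unname(prior["BG.400"]), "+")
  expect_equal(unname(prior["IND.300"]), "+")
  expect_equal(unname(prior["DIST.TACZ"]), "-")
  expect_equal(unname(prior["LNDIST.PRSC"]), "+")
  expect_equal(unname(prior["DIST.RES"]), "+")   # opposite of RES "-"
  expect_equal(unname(prior["DIST.HW"]), "-")    # opposite of traffic "+"
  expect_equal(unname(prior["DIST.HZRFAC"]), "none")
  expect_equal(unname(prior["BGD.400"]), "+")
  expect_equal(unname(prior["TPDC.2500"]), "+")
  expect_true(all(catal$sign_prior[catal$class == "product"] == "+"))
})

test_that("a scene missing a layer kind is refused by name", {
  scene <- tiny_scene()
  maimed <- scene
  maimed$bridges <- vector_layer()
  expect_error(build_catalog(maimed), "bridges")
})

test_that("product variables follow the floored-ratio construction", {
  scene <- tiny_scene()
  cs <- scene$cell_size
  bgd <- compute_ppv("BGD.400", scene)
  tmpl <- grid_template(scene$extent, cs)
  pres <- rasterize(scene$bridges, tmpl, "presence")
  manual <- focal_sum(pres, 400)$values * cs /
    pmax(euclidean_distance(pres)$values, cs)
  expect_equal(bgd$values, manual, tolerance = 1e-9)
  # squared-distance variant divides by the squared floored distance
  bgsqd <- compute_ppv("BGSQD.400", scene)
  expect_equal(bgsqd$values,
               manual / pmax(euclidean_distance(pres)$values, cs),
               tolerance = 1e-9)
  expect_true(all(is.finite(bgd$values)))
})

test_that("empty feature layers give zero areas but undefined distances", {
  scene <- tiny_scene()
  no_grs <- scene
  keep <- vl_attr(scene$landuse, "type") != "GRS"
  no_grs$landuse <- vector_layer(scene$landuse$features[keep])
  expect_warning(g <- compute_ppv("GRS.300", no_grs), "empty layer")
  expect_equal(sum(g$values), 0)
  expect_error(suppressWarnings(compute_ppv("DIST.GRS", no_grs)),
               "no feature cells")
})

test_that("every catalog raster is finite everywhere", {
  scene <- tiny_scene()
  catal <- build_catalog(scene, recovery_radii())
  rasters <- compute_ppv_rasters(catal, scene)
  expect_true(all(vapply(rasters, function(g) all(is.finite(g$values)),
                         logical(1))))
})

test_that("station extraction is exact, order-preserving and guarded", {
  scene <- tiny_scene()
  rasters <- compute_ppv_rasters(c("DIST.TACZ", "GRS.300", "SLP"), scene)
  st <- place_stations(scene, 8, seed = 20)
  des <- extract_station_values(rasters, st)
  expect_equal(nrow(des), 8)
  # station placed exactly at a cell centre picks that cell's value
  cc <- cell_centers(rasters$SLP)
  st1 <- data.frame(station_id = "C", x = cc$x[10], y = cc$y[15])
  d1 <- extract_station_values(rasters, st1)
  expect_identical(d1$SLP, rasters$SLP$values[15, 10])
  # permuting stations permutes rows only
  perm <- sample(nrow(st))
  des_p <- extract_station_values(rasters, st[perm, ])
  expect_equal(des_p$GRS.300, des$GRS.300[perm])
  # outside station is named in the error
  bad <- rbind(st, data.frame(station_id = "FAR", x = -50, y = 50))
  expect_error(extract_station_values(rasters, bad), "FAR")
})

test_that("ppv name parsing covers every class and rejects nonsense", {
  expect_equal(parse_ppv_name("RDa.750")$class, "traffic")
  expect_equal(parse_ppv_name("TPDC.2500")$kind, "tpdc")
  expect_equal(parse_ppv_name("STSQD.300")$kind, "product_sq")
  expect_equal(parse_ppv_name("LNDIST.OTHR")$sign_prior, "none")
  expect_error(parse_ppv_name("NOPE.100"), "unknown")
})
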