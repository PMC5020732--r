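# End-to-end orchestration: synthetic city -> hourly simulation with gaps
# -> multiple imputation -> PPV design table -> nine constrained stepwise
# models (3 pollutants x annual/cooler/warmer) -> stability and spatial
# autocorrelation diagnostics -> clipped regression maps -> seasonal
# comparison at random locations. Each stage writes plain-text outputs to
# the run directory and is skipped when its outputs already exist, so
# deleting one stage's files regenerates only that stage and those after
# it.

#' Pipeline configuration
#'
#' @param master_seed single integer; per-stage seeds are derived from it
#'   by fixed offsets (city +101, stations +211, simulation +307,
#'   imputation +401, location sampling +503).
#' @param city named list of [city_config()] overrides.
#' @param n_stations number of monitoring stations.
#' @param truth ground truth (see [default_truth()]).
#' @param missing_rates named per-pollutant missingness rates; the defaults
#'   match regulatory-network gap rates of about 28%.
#' @param missing_mechanism `"block"` (contiguous instrument outages,
#'   default here for realism) or `"mcar"`.
#' @param n_runs imputation runs to average.
#' @param radii [ppv_radii()] configuration.
#' @param alpha_p,vif_max selection gates.
#' @param linearize apply predictor linearization before selection.
#' @param n_sample_points locations for the seasonal comparison.
#' @param map_cell_size raster resolution for prediction maps (defaults to
#'   the city cell size).
#' @return a config list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L, city = list(), n_stations = 12L,
                            truth = default_truth(),
                            missing_rates = c(no = 0.281, no2 = 0.277,
                                              nox = 0.276),
                            missing_mechanism = "block", n_runs = 10L,
                            radii = ppv_radii(), alpha_p = 0.1, vif_max = 5,
                            linearize = TRUE, n_sample_points = 1000L,
                            map_cell_size = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline config from YAML
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown pipeline config fields: ", paste(bad, collapse = ", "))
  if (!is.null(raw$missing_rates)) raw$missing_rates <- unlist(raw$missing_rates)
  if (!is.null(raw$radii)) raw$radii <- do.call(ppv_radii, raw$radii)
  if (!is.null(raw$truth)) stop("truth cannot be configured from YAML; use R")
  do.call(pipeline_config, raw)
}

stage_done <- function(paths) all(file.exists(paths))

pipeline_scene <- function(config) {
  generate_city(do.call(city_config, config$city),
                seed = config$master_seed + 101L)
}

MODEL_PERIODS <- c("annual", "cooler", "warmer")
MODEL_POLLUTANTS <- c("no", "no2", "nox")

#' Reconstruct a mappable model from its JSON serialization
#' @param path path written by [write_model_json()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform <- structure(list(power = obj$transform$power,
                              branch = obj$transform$branch),
                         class = "lur_transform")
  terms <- as.data.frame(obj$terms, stringsAsFactors = FALSE)
  if (!nrow(terms)) terms <- data.frame(name = character(0), coef = numeric(0))
  ppv_tr <- lapply(obj$ppv_transforms, function(t)
    list(tag = t$tag, eps = t$eps))
  structure(list(label = obj$label, transform = transform, terms = terms,
                 intercept = obj$intercept, ppv_transforms = ppv_tr,
                 stats = obj$stats, n = obj$n, cap = obj$cap,
                 alpha_p = obj$alpha_p, vif_max = obj$vif_max,
                 trace = obj$trace),
            class = "lur_model")
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param force recompute every stage even if outputs exist.
#' @param verbose log stage progress and wall time.
#' @return invisibly, the run directory.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, verbose = TRUE) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  logf <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, outputs, fun) {
    if (!force && stage_done(outputs)) {
      logf("[%s] cached", name)
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    fun()
    logf("[%s] done in %.1f s", name, proc.time()[3] - t0)
  }
  seed <- config$master_seed
  scene <- NULL
  get_scene <- function() {
    if (is.null(scene)) scene <<- pipeline_scene(config)
    scene
  }

  p_stations <- file.path(out_dir, "stations.csv")
  p_hourly <- file.path(out_dir, "hourly.csv")
  p_resp <- file.path(out_dir, "responses.csv")
  p_design <- file.path(out_dir, "design.csv")
  p_catalog <- file.path(out_dir, "catalog.json")
  p_models <- file.path(out_dir, "models",
                        sprintf("%s_%s.json",
                                rep(MODEL_PERIODS, each = 3),
                                rep(MODEL_POLLUTANTS, 3)))
  p_summary <- file.path(out_dir, "summary_models.csv")
  p_diag <- file.path(out_dir, "diagnostics.json")
  p_maps <- file.path(out_dir, "maps",
                      sub("json$", "asc", basename(p_models)))
  p_clip <- file.path(out_dir, "clip_report.csv")
  p_seasonal <- file.path(out_dir, "seasonal.json")

  stage("synth", p_stations, function() {
    sc <- get_scene()
    st <- place_stations(sc, config$n_stations, seed = seed + 211L)
    utils::write.csv(st, p_stations, row.names = FALSE)
    write_geojson(sc$roads, file.path(out_dir, "roads.geojson"))
    write_geojson(sc$landuse, file.path(out_dir, "landuse.geojson"))
    write_geojson(sc$facilities, file.path(out_dir, "facilities.geojson"))
    write_ascii_grid(sc$dem, file.path(out_dir, "dem.asc"))
  })
  stations <- utils::read.csv(p_stations, stringsAsFactors = FALSE)

  stage("measure", p_hourly, function() {
    series <- simulate_concentrations(get_scene(), stations, config$truth,
                                      seed = seed + 307L)
    series <- apply_missingness(series, config$missing_rates,
                                config$missing_mechanism, seed = seed + 307L)
    write_hourly_csv(series, p_hourly)
  })

  stage("impute", p_resp, function() {
    series <- read_hourly_csv(p_hourly)
    out <- list()
    for (pol in MODEL_POLLUTANTS) {
      sm <- series_to_matrix(series, pol)
      imp <- em_bootstrap_impute(sm$y, timestamps = sm$timestamps,
                                 n_runs = config$n_runs, seed = seed + 401L)
      means <- seasonal_means(imp)
      means$pollutant <- pol
      out[[pol]] <- means
    }
    utils::write.csv(do.call(rbind, out), p_resp, row.names = FALSE)
  })

  stage("ppv", c(p_design, p_catalog), function() {
    sc <- get_scene()
    catalog <- build_catalog(sc, config$radii)
    write_catalog_json(catalog, p_catalog)
    cell <- if (is.null(config$map_cell_size)) sc$cell_size else
      config$map_cell_size
    rasters <- compute_ppv_rasters(catalog, sc, cell)
    resp <- utils::read.csv(p_resp, stringsAsFactors = FALSE)
    wide <- stats::reshape(resp, direction = "wide", idvar = "station_id",
                           timevar = "pollutant")
    names(wide) <- sub("^(annual|cooler|warmer)\\.(no2|nox|no)$", "\\1_\\2",
                       names(wide))
    design <- extract_station_values(rasters, stations, wide)
    utils::write.csv(design, p_design, row.names = FALSE)
  })

  stage("fit", c(p_models, p_summary), function() {
    design <- utils::read.csv(p_design, stringsAsFactors = FALSE)
    catalog <- jsonlite::read_json(p_catalog, simplifyVector = TRUE)
    priors <- stats::setNames(catalog$sign_prior, catalog$name)
    summary_rows <- list()
    for (period in MODEL_PERIODS) for (pol in MODEL_POLLUTANTS) {
      label <- sprintf("%s_%s", period, pol)
      y <- design[[label]]
      tr <- select_response_transform(y)
      des <- design
      ppv_tr <- NULL
      cand <- intersect(catalog$name, names(design))
      if (config$linearize) {
        lin <- linearize_ppvs(design, transform_apply(tr, y), cand)
        des <- lin$design_t
        ppv_tr <- lin$transforms
        cand <- setdiff(cand, lin$excluded)
      }
      model <- forward_select(des, y, priors[cand],
                              alpha_p = config$alpha_p,
                              vif_max = config$vif_max, transform = tr,
                              ppv_transforms = ppv_tr, label = label)
      write_model_json(model,
                       file.path(out_dir, "models",
                                 sprintf("%s.json", label)))
      s <- model$stats
      summary_rows[[label]] <- data.frame(
        model = label, equation = equation_string(model),
        n_terms = nrow(model$terms), r2 = s$r2, adj_r2 = s$adj_r2,
        loocv_r2 = s$loocv_r2, rmse_ppb = s$rmse, max_vif = s$max_vif,
        max_vif_var = ifelse(is.na(s$max_vif_var), "", s$max_vif_var),
        shapiro_p = s$shapiro_p, stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, summary_rows), p_summary,
                     row.names = FALSE)
  })

  stage("diagnose", p_diag, function() {
    design <- utils::read.csv(p_design, stringsAsFactors = FALSE)
    diag <- list()
    for (mp in p_models) {
      model <- read_model_json(mp)
      label <- model$label
      if (!nrow(model$terms)) {
        diag[[label]] <- list(note = "empty model, no diagnostics")
        next
      }
      y <- design[[label]]
      des <- design
      for (nm in names(model$ppv_transforms)) {
        tr <- model$ppv_transforms[[nm]]
        if (!is.null(tr$tag) && tr$tag != "identity")
          des[[nm]] <- ppv_transform_fun(tr$tag, tr$eps)(design[[nm]])
      }
      model$y <- y
      stab <- loocv_coefficient_stability(des, model)
      yt <- transform_apply(model$transform, y)
      st <- fit_stats(des, yt, model$terms$name)
      mi <- morans_i(st$residuals, cbind(design$x, design$y))
      diag[[label]] <- list(
        stability = stab,
        morans_i = list(I = mi$I, expected = mi$expected, sd = mi$sd,
                        p_value = mi$p_value, weights = mi$weights))
    }
    jsonlite::write_json(diag, p_diag, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  })

  stage("map", c(p_maps, p_clip), function() {
    sc <- get_scene()
    design <- utils::read.csv(p_design, stringsAsFactors = FALSE)
    cell <- if (is.null(config$map_cell_size)) sc$cell_size else
      config$map_cell_size
    clips <- list()
    for (mp in p_models) {
      model <- read_model_json(mp)
      label <- model$label
      terms <- model$terms$name
      rasters <- if (length(terms)) compute_ppv_rasters(terms, sc, cell) else
        list(domain = grid_template(sc$extent, cell))
      pred <- predict_surface(model, rasters)
      obs <- design[[label]]
      clip <- clip_predictions(pred, min(obs), max(obs))
      write_ascii_grid(clip$raster,
                       file.path(out_dir, "maps",
                                 sprintf("%s.asc", label)))
      clips[[label]] <- clip
    }
    utils::write.csv(clip_report(clips), p_clip, row.names = FALSE)
  })

  stage("seasons", p_seasonal, function() {
    out <- list()
    for (pol in MODEL_POLLUTANTS) {
      maps <- list(
        annual = read_ascii_grid(file.path(out_dir, "maps",
                                           sprintf("annual_%s.asc", pol))),
        cooler = read_ascii_grid(file.path(out_dir, "maps",
                                           sprintf("cooler_%s.asc", pol))),
        warmer = read_ascii_grid(file.path(out_dir, "maps",
                                           sprintf("warmer_%s.asc", pol))))
      n_pts <- min(config$n_sample_points,
                   sum(!is.na(maps$annual$values)))
      pts <- sample_locations(maps$annual, n_pts, seed = seed + 503L)
      out[[pol]] <- tryCatch({
        cc <- correlate_predictions(maps, pts)
        list(correlation = cc$correlation, method = cc$method, n = cc$n)
      }, error = function(e)
        # e.g. a flat surface from an intercept-only model
        list(note = conditionMessage(e)))
    }
    jsonlite::write_json(out, p_seasonal, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  invisible(out_dir)
}
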