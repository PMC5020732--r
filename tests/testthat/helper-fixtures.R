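# Shared fixtures: a small city scene built once per test run, and small
# helpers used across files.

tiny_config <- function(...) {
  city_config(extent = 1500, cell_size = 30, block_size = 250,
              n_bridges = 8, taczone_radius = 300,
              facilities_per_kind = c(
                primary_school = 8, high_school = 5, petrol_station = 5,
                bus_terminal = 3, airport = 1, hazardous_facility = 3,
                mosque = 6, park = 5, food_shop = 10, ambulance = 4,
                sport_land = 4), ...)
}

.fixture_env <- new.env()

tiny_scene <- function() {
  if (is.null(.fixture_env$scene))
    .fixture_env$scene <- generate_city(tiny_config(), seed = 42)
  .fixture_env$scene
}

log_transform <- function() {
  structure(list(power = 1, branch = 1, shapiro_p_log = NA_real_,
                 candidate_p = NULL, alpha = 0.05),
            class = "lur_transform")
}

# quiet truth: no stochastic or deterministic extras, for closed-form checks
quiet_truth <- function(active, base_level = 40) {
  ground_truth(active = active, noise_sd = 0, shared_sd = 0,
               diurnal_amp = 0, base_level = base_level)
}

brute_force_loocv <- function(design, y, variables) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    df <- design[-i, c(variables), drop = FALSE]
    df$.y <- y[-i]
    fit <- stats::lm(.y ~ ., data = df)
    pred <- unname(stats::predict(fit, design[i, variables, drop = FALSE]))
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

brute_force_edt <- function(presence) {
  v <- presence$values
  cs <- presence$cell_size
  feat <- which(v > 0, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (r in seq_len(nrow(v))) for (c in seq_len(ncol(v))) {
    out[r, c] <- cs * sqrt(min((feat[, 1] - r)^2 + (feat[, 2] - c)^2))
  }
  out
}

brute_force_moran <- function(z, W) {
  n <- length(z)
  z <- z - mean(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}
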