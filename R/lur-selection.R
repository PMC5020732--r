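# Constrained forward stepwise selection for land use regression. The
# response is log-transformed and, if still non-normal, raised to a power
# chosen to maximize Shapiro-Wilk normality; predictor relationships are
# linearized with log/power transforms; then variables are added one at a
# time under four simultaneous gates - a-priori effect direction for every
# variable in the model, p < 0.1 for every variable, a strict increase in
# leave-one-out cross-validated R^2, and a variance inflation factor below
# threshold - with the model size capped at the square root of the number
# of stations.

# -- response transform ------------------------------------------------------

#' Select the response transform
#'
#' Takes the natural log of the response; if the Shapiro-Wilk test rejects
#' normality of log(y) at `alpha`, chooses the power p from the candidate
#' set that maximizes the Shapiro-Wilk p-value of (log y)^p.
#'
#' @param y positive response vector, n >= 8.
#' @param alpha normality test level (default 0.05).
#' @param candidates candidate powers; the default covers the exponents
#'   that arise in practice for seasonal nitrogen-oxide means.
#' @return an object of class `lur_transform` with fields `power`,
#'   `shapiro_p_log`, `candidate_p` and the sign branch used for inversion.
#' @export
select_response_transform <- function(y, alpha = 0.05,
                                      candidates = c(-4, -3, -2, -1, 2, 3)) {
  if (any(!is.finite(y)) || any(y <= 0)) stop("response must be positive")
  if (length(y) < 8L) stop("need at least 8 observations")
  if (stats::sd(y) == 0) stop("constant response: normality test undefined")
  ly <- log(y)
  p_log <- stats::shapiro.test(ly)$p.value
  cand_p <- stats::setNames(rep(NA_real_, length(candidates)),
                            as.character(candidates))
  power <- 1
  if (p_log < alpha) {
    for (p in candidates) {
      tv <- ly^p
      if (any(!is.finite(tv)) || stats::sd(tv) == 0) next
      cand_p[as.character(p)] <- stats::shapiro.test(tv)$p.value
    }
    if (any(is.finite(cand_p)) && max(cand_p, na.rm = TRUE) > p_log)
      power <- candidates[which.max(cand_p)]
  }
  structure(list(power = power, shapiro_p_log = p_log,
                 candidate_p = cand_p, alpha = alpha,
                 branch = sign(mean(ly))),
            class = "lur_transform")
}

#' Apply / invert a response transform
#'
#' `t(y) = (log y)^p`. Inversion takes the real p-th root: for odd powers
#' the sign of t determines the sign of log y; for even powers the branch
#' recorded at fit time (the sign of the observed log responses) is used,
#' and non-positive t is not invertible (returned as `NA`).
#'
#' @param transform a `lur_transform`.
#' @param y,t response values on the raw (ppb) / transformed scale.
#' @export
transform_apply <- function(transform, y) log(y)^transform$power

#' @rdname transform_apply
#' @export
transform_invert <- function(transform, t) {
  p <- transform$power
  if (p == 1) return(exp(t))
  out <- rep(NA_real_, length(t))
  if (p %% 2 == 1) { # odd power: sign carries through
    ok <- is.finite(t) & t != 0
    out[ok] <- exp(sign(t[ok]) * abs(t[ok])^(1 / p))
    if (p > 0) out[is.finite(t) & t == 0] <- 1
  } else { # even power: t must be positive, use the recorded branch
    ok <- is.finite(t) & t > 0
    out[ok] <- exp(transform$branch * abs(t[ok])^(1 / p))
    if (p > 0) out[is.finite(t) & t == 0] <- 1
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' @export
print.lur_transform <- function(x, ...) {
  cat(sprintf("<lur_transform> t(y) = (log y)^%g (Shapiro-Wilk p of log y: %.3g)\n",
              x$power, x$shapiro_p_log))
  invisible(x)
}

# -- PPV linearization -------------------------------------------------------

ppv_transform_fun <- function(tag, eps = 1) {
  switch(tag,
         identity = function(x) x,
         log = function(x) log(x + eps),
         pow0.1 = function(x) x^0.1,
         pow0.5 = function(x) x^0.5,
         pow2 = function(x) x^2,
         stop("unknown PPV transform: ", tag))
}

#' Linearize predictor-response relationships
#'
#' For each candidate predictor, picks the transform among identity,
#' log(x + eps), x^0.1, x^0.5 and x^2 that maximizes the absolute Pearson
#' correlation with the transformed response; ties keep the identity.
#' Zero-variance predictors are flagged and excluded from candidacy.
#'
#' @param design design data.frame.
#' @param response_t numeric vector: the transformed response.
#' @param ppv_cols character vector of predictor column names.
#' @return list with `design_t` (transformed columns), `transforms` (named
#'   list of tag + eps), `excluded` (zero-variance names), `cor` (chosen
#'   absolute correlations).
#' @export
linearize_ppvs <- function(design, response_t, ppv_cols) {
  design_t <- design
  transforms <- list()
  excluded <- character(0)
  cors <- stats::setNames(numeric(0), character(0))
  tags <- c("identity", "log", "pow0.1", "pow0.5", "pow2")
  for (nm in ppv_cols) {
    x <- design[[nm]]
    if (stats::sd(x) == 0) {
      excluded <- c(excluded, nm)
      next
    }
    eps <- if (any(x > 0)) min(x[x > 0]) / 2 else 1
    best_tag <- "identity"
    best_r <- abs(stats::cor(x, response_t))
    for (tag in tags[-1]) {
      if (min(x) < 0 && tag %in% c("log", "pow0.1", "pow0.5")) next
      xt <- ppv_transform_fun(tag, eps)(x)
      if (any(!is.finite(xt)) || stats::sd(xt) == 0) next
      r <- abs(stats::cor(xt, response_t))
      if (is.finite(r) && r > best_r + 1e-10) {
        best_r <- r
        best_tag <- tag
      }
    }
    transforms[[nm]] <- list(tag = best_tag, eps = eps)
    design_t[[nm]] <- ppv_transform_fun(best_tag, eps)(x)
    cors[nm] <- best_r
  }
  list(design_t = design_t, transforms = transforms, excluded = excluded,
       cor = cors)
}

# -- core statistics ---------------------------------------------------------

design_matrix <- function(design, variables) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(design[, variables, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Leave-one-out cross-validated R-squared
#'
#' 1 - PRESS/TSS with PRESS computed through the hat-matrix shortcut
#' (e_i / (1 - h_ii)), identical to refitting the model n times with one
#' row held out. May be negative. With no variables, scores the
#' intercept-only model.
#'
#' @param design design data.frame.
#' @param response response column name or numeric vector.
#' @param variables character vector of predictor columns.
#' @return a single number.
#' @export
loocv_r2 <- function(design, response, variables = character(0)) {
  y <- if (is.character(response)) design[[response]] else response
  n <- length(y)
  if (n <= length(variables) + 1L)
    stop("need n > #variables + 1 for LOOCV")
  X <- design_matrix(design, variables)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design in loocv_r2")
  fit <- qr.coef(qx, y)
  res <- y - X %*% fit
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-12)) return(-Inf) # a row fully determines its fit
  press <- sum((res / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  1 - press / tss
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the remaining
#' predictors. A single predictor has VIF 1 by convention; exact
#' collinearity reports `Inf`.
#'
#' @param design design data.frame.
#' @param variables character vector of predictor columns (>= 1).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design, variables) {
  if (length(variables) < 2L)
    return(stats::setNames(rep(1, length(variables)), variables))
  out <- stats::setNames(numeric(length(variables)), variables)
  for (j in seq_along(variables)) {
    yj <- design[[variables[j]]]
    Xj <- design_matrix(design, variables[-j])
    qx <- qr(Xj)
    res <- qr.resid(qx, yj)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - sum(res^2) / tss
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Shapiro-Wilk check of model residuals
#'
#' The final-model gate: the model is flagged, not rejected, when the
#' residuals fail the normality test.
#'
#' @param residuals numeric residual vector (n >= 3).
#' @param alpha flag level.
#' @return list with `statistic`, `p_value`, `flagged`.
#' @export
residual_normality <- function(residuals, alpha = 0.05) {
  if (length(residuals) < 3L) stop("need at least 3 residuals")
  if (stats::sd(residuals) < 1e-12)
    stop("degenerate (near-zero) residuals: normality test undefined")
  sw <- stats::shapiro.test(residuals)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       flagged = sw$p.value < alpha)
}

# -- forward selection -------------------------------------------------------

fit_stats <- function(design, response_t, variables) {
  X <- design_matrix(design, variables)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL) # collinear candidate set
  cf <- qr.coef(qx, response_t)
  res <- response_t - X %*% cf
  n <- length(response_t); k <- length(variables)
  rss <- sum(res^2); tss <- sum((response_t - mean(response_t))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  sigma2 <- rss / (n - k - 1)
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(X))),
                      error = function(e) NULL)
  if (is.null(XtX_inv)) return(NULL)
  se <- stats::setNames(sqrt(pmax(diag(XtX_inv) * sigma2, 0)), colnames(X))
  tval <- cf / se
  pval <- 2 * stats::pt(abs(tval), df = n - k - 1, lower.tail = FALSE)
  list(coef = cf, se = se, p = pval, r2 = r2, adj_r2 = adj,
       residuals = as.numeric(res), fitted = as.numeric(X %*% cf))
}

signs_ok <- function(coef, variables, priors) {
  for (v in variables) {
    pr <- priors[[v]]
    if (is.null(pr) || pr == "none") next
    if (pr == "+" && coef[[v]] <= 0) return(v)
    if (pr == "-" && coef[[v]] >= 0) return(v)
  }
  NULL
}

#' Constrained forward stepwise selection
#'
#' At every iteration each not-yet-included predictor is evaluated in the
#' model alongside the already-selected ones; a candidate survives only if
#' (i) every coefficient in the resulting model matches its a-priori sign
#' where one is assigned, (ii) every predictor has p < `alpha_p`,
#' (iii) the leave-one-out cross-validated R^2 strictly increases, and
#' (iv) the largest variance inflation factor stays below `vif_max`. Among
#' survivors the one with the highest adjusted R^2 enters (ties broken by
#' lower maximum VIF, then candidate order). Selection stops when no
#' candidate survives or the model reaches `cap` terms (default: the
#' ceiling of the square root of the number of stations). The final model
#' is checked for residual normality and every candidate evaluation is
#' recorded in the trace.
#'
#' @param design design data.frame containing the (raw, positive) response
#'   column and predictor columns (already linearized if desired).
#' @param response name of the response column, or a numeric vector.
#' @param priors named character vector of sign priors (`"+"`, `"-"`,
#'   `"none"`); its names define the candidate set.
#' @param alpha_p per-variable p-value gate (default 0.1).
#' @param vif_max VIF threshold (default 5).
#' @param cap maximum number of terms; default `ceiling(sqrt(n))`.
#' @param transform a `lur_transform` for the response, or NULL to select
#'   one with [select_response_transform()].
#' @param ppv_transforms optional named list of per-predictor transform
#'   records (from [linearize_ppvs()]), stored for later mapping.
#' @param alpha_norm level for the residual-normality flag.
#' @param label optional model label (e.g. "annual NO").
#' @return an object of class `lur_model`. If no admissible first variable
#'   exists, an empty (intercept-only) model is returned, with the trace
#'   explaining each rejection.
#' @export
forward_select <- function(design, response, priors, alpha_p = 0.1,
                           vif_max = 5, cap = NULL, transform = NULL,
                           ppv_transforms = NULL, alpha_norm = 0.05,
                           label = NULL) {
  y_raw <- if (is.character(response)) design[[response]] else response
  n <- length(y_raw)
  if (n < 8L) stop("need at least 8 stations")
  if (is.null(cap)) cap <- ceiling(sqrt(n))
  if (cap < 1L) stop("cap must be >= 1")
  if (is.null(transform)) transform <- select_response_transform(y_raw)
  yt <- transform_apply(transform, y_raw)

  candidates <- intersect(names(priors), names(design))
  selected <- character(0)
  cur_loocv <- loocv_r2(design, yt, selected)
  trace <- list()
  note <- function(iter, cand, decision, adj = NA, lo = NA, mv = NA,
                   pmax_ = NA) {
    trace[[length(trace) + 1L]] <<- data.frame(
      iteration = iter, candidate = cand, decision = decision,
      adj_r2 = adj, loocv_r2 = lo, max_vif = mv, max_p = pmax_,
      stringsAsFactors = FALSE)
  }

  iter <- 0L
  while (length(selected) < cap) {
    iter <- iter + 1L
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    survivors <- data.frame(candidate = character(0), adj_r2 = numeric(0),
                            loocv = numeric(0), max_vif = numeric(0),
                            ord = integer(0))
    for (ci in seq_along(pool)) {
      cand <- pool[ci]
      vars <- c(selected, cand)
      if (stats::sd(design[[cand]]) == 0) {
        note(iter, cand, "zero_variance")
        next
      }
      st <- fit_stats(design, yt, vars)
      if (is.null(st)) {
        note(iter, cand, "collinear")
        next
      }
      bad <- signs_ok(st$coef, vars, priors)
      if (!is.null(bad)) {
        note(iter, cand, sprintf("sign(%s)", bad), st$adj_r2)
        next
      }
      pmax_ <- max(st$p[vars])
      if (pmax_ >= alpha_p) {
        note(iter, cand, "p_value", st$adj_r2, pmax_ = pmax_)
        next
      }
      lo <- loocv_r2(design, yt, vars)
      if (!(lo > cur_loocv)) {
        note(iter, cand, "loocv", st$adj_r2, lo, pmax_ = pmax_)
        next
      }
      mv <- max(vif(design, vars))
      if (!(mv < vif_max)) {
        note(iter, cand, "vif", st$adj_r2, lo, mv, pmax_)
        next
      }
      note(iter, cand, "admissible", st$adj_r2, lo, mv, pmax_)
      survivors <- rbind(survivors, data.frame(
        candidate = cand, adj_r2 = st$adj_r2, loocv = lo, max_vif = mv,
        ord = ci, stringsAsFactors = FALSE))
    }
    if (!nrow(survivors)) break
    pick <- survivors[order(-survivors$adj_r2, survivors$max_vif,
                            survivors$ord), ][1L, ]
    selected <- c(selected, pick$candidate)
    cur_loocv <- pick$loocv
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = iter, candidate = pick$candidate, decision = "accepted",
      adj_r2 = pick$adj_r2, loocv_r2 = pick$loocv, max_vif = pick$max_vif,
      max_p = NA, stringsAsFactors = FALSE)
  }

  st <- fit_stats(design, yt, selected)
  vifs <- if (length(selected)) vif(design, selected) else numeric(0)
  max_vif <- if (length(vifs)) max(vifs) else NA_real_
  max_vif_var <- if (length(vifs)) names(vifs)[which.max(vifs)] else NA_character_
  norm <- if (length(selected) && stats::sd(st$residuals) > 1e-12)
    residual_normality(st$residuals, alpha_norm)
  else list(statistic = NA_real_, p_value = NA_real_, flagged = FALSE)
  yhat <- transform_invert(transform, st$fitted)
  rmse <- sqrt(mean((y_raw - yhat)^2, na.rm = TRUE))
  model_p <- if (length(selected)) {
    f <- (st$r2 / length(selected)) /
      ((1 - st$r2) / (n - length(selected) - 1))
    stats::pf(f, length(selected), n - length(selected) - 1,
              lower.tail = FALSE)
  } else NA_real_

  terms <- data.frame(
    name = selected,
    coef = if (length(selected)) unname(st$coef[selected]) else numeric(0),
    se = if (length(selected)) unname(st$se[selected]) else numeric(0),
    p_value = if (length(selected)) unname(st$p[selected]) else numeric(0),
    sign_prior = if (length(selected))
      unname(vapply(selected, function(v)
        if (is.null(priors[[v]])) "none" else priors[[v]], "")) else
      character(0),
    stringsAsFactors = FALSE)

  structure(list(
    label = label, transform = transform, terms = terms,
    intercept = unname(st$coef[["(Intercept)"]]),
    ppv_transforms = ppv_transforms[selected],
    stats = list(r2 = st$r2, adj_r2 = st$adj_r2, loocv_r2 = cur_loocv,
                 rmse = rmse, max_vif = max_vif, max_vif_var = max_vif_var,
                 shapiro_w = norm$statistic, shapiro_p = norm$p_value,
                 normality_flagged = norm$flagged, model_p = model_p),
    n = n, cap = cap, alpha_p = alpha_p, vif_max = vif_max,
    trace = do.call(rbind, trace),
    residuals = st$residuals, fitted_t = st$fitted, y = y_raw),
    class = "lur_model")
}

#' Human-readable model equation
#' @param model a `lur_model`.
#' @export
equation_string <- function(model) {
  p <- model$transform$power
  lhs <- if (p == 1) "log(y)" else sprintf("(log y)^%g", p)
  if (!nrow(model$terms))
    return(sprintf("%s = %.3g", lhs, model$intercept))
  term_lab <- vapply(model$terms$name, function(nm) {
    tr <- model$ppv_transforms[[nm]]
    if (is.null(tr) || tr$tag == "identity") return(nm)
    switch(tr$tag,
           log = sprintf("log(%s)", nm),
           pow0.1 = sprintf("(%s)^0.1", nm),
           pow0.5 = sprintf("sqrt(%s)", nm),
           pow2 = sprintf("(%s)^2", nm), nm)
  }, "")
  rhs <- sprintf("%.2e x %s", abs(model$terms$coef), term_lab)
  signs <- ifelse(model$terms$coef >= 0, "+ ", "- ")
  sprintf("%s = %.3g %s", lhs, model$intercept,
          paste(paste0(signs, rhs), collapse = " "))
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("<lur_model> %s: %d terms (cap %d), n = %d\n",
              if (is.null(x$label)) "model" else x$label,
              nrow(x$terms), x$cap, x$n))
  cat(" ", equation_string(x), "\n")
  s <- x$stats
  cat(sprintf("  R2 %.3f | adj R2 %.3f | LOOCV R2 %.3f | RMSE %.1f ppb | max VIF %.2f (%s)\n",
              s$r2, s$adj_r2, s$loocv_r2, s$rmse, s$max_vif,
              ifelse(is.na(s$max_vif_var), "-", s$max_vif_var)))
  invisible(x)
}

#' Audit a selection trace against the model constraints
#'
#' Verifies, from the stored trace and final fit, that the accepted model
#' satisfies all five constraints simultaneously: sign priors, per-variable
#' p-values below the gate, a strictly increasing LOOCV path, maximum VIF
#' below threshold, and the size cap.
#'
#' @param model a `lur_model`.
#' @return named logical vector; all TRUE for a compliant model.
#' @export
audit_selection <- function(model) {
  tr <- model$trace
  acc <- tr[tr$decision == "accepted", , drop = FALSE]
  sign_ok <- !nrow(model$terms) || all(
    model$terms$sign_prior == "none" |
    (model$terms$sign_prior == "+" & model$terms$coef > 0) |
    (model$terms$sign_prior == "-" & model$terms$coef < 0))
  p_ok <- !nrow(model$terms) || all(model$terms$p_value < model$alpha_p)
  loocv_path <- acc$loocv_r2
  loocv_ok <- length(loocv_path) <= 1 || all(diff(loocv_path) > 0)
  vif_ok <- is.na(model$stats$max_vif) || model$stats$max_vif < model$vif_max
  cap_ok <- nrow(model$terms) <= model$cap
  c(signs = sign_ok, p_values = p_ok, loocv_monotone = loocv_ok,
    vif = vif_ok, cap = cap_ok)
}

#' Serialize a model to JSON
#' @param model a `lur_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    label = model$label,
    equation = equation_string(model),
    transform = list(power = model$transform$power,
                     branch = model$transform$branch),
    intercept = model$intercept,
    terms = model$terms,
    ppv_transforms = lapply(model$ppv_transforms, function(t)
      list(tag = t$tag, eps = t$eps)),
    stats = model$stats, n = model$n, cap = model$cap,
    alpha_p = model$alpha_p, vif_max = model$vif_max,
    trace = model$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
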