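# Supervised stepwise linear-regression LUR in the ESCAPE tradition:
# forward selection maximizing adjusted R^2, with a minimum-gain rule,
# a-priori coefficient sign constraints per predictor group, removal of
# terms insignificant at p > 0.10, and a variance-inflation-factor guard
# against collinearity. Used both as the local reference model and as the
# directly-applied (no re-estimation) cross-city baseline.

#' Default coefficient sign constraints by predictor name
#'
#' Traffic, road-length, industry, port, airport, transportation,
#' residential and population predictors are constrained positive; natural,
#' urban-green, agricultural and water predictors negative; anything else is
#' unconstrained.
#'
#' @param columns Character vector of predictor names.
#' @return Named character vector with values `"+"`, `"-"` or `"any"`.
#' @export
default_sign_constraints <- function(columns) {
  pos <- "^(traffic|hd_traffic|roadlength|industry|port|airport|transportation|residential|population)"
  neg <- "^(natural|urban_green|agricultural|water)"
  out <- rep("any", length(columns))
  out[grepl(pos, columns)] <- "+"
  out[grepl(neg, columns)] <- "-"
  stats::setNames(out, columns)
}

.sign_ok <- function(beta, constraint) {
  switch(constraint, "+" = beta > 0, "-" = beta < 0, TRUE)
}

# Variance inflation factors of a predictor set: diag of the inverse
# correlation matrix.
.vif <- function(X) {
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  R <- stats::cor(X)
  diag(solve(R))
}

#' Fit a stepwise linear-regression LUR model
#'
#' Forward selection over the candidate predictors: at each step the
#' candidate giving the largest adjusted-R^2 gain is added, provided the gain
#' is at least `gain_min`, its coefficient sign matches its constraint,
#' every previously selected coefficient keeps its sign, and no variance
#' inflation factor among the selected set exceeds `vif_max`. After
#' selection, predictors with p > `p_drop` are removed one at a time
#' (largest p first). Candidates are scanned in alphabetical order, so the
#' fit does not depend on the column order of `X` and ties on equal gain go
#' to the alphabetically first name.
#'
#' @param X Data.frame or matrix of candidate predictors (numeric, finite).
#' @param y Numeric response (per-segment aggregate concentrations).
#' @param constraints Named character vector of sign constraints (`"+"`,
#'   `"-"`, `"any"`); default [default_sign_constraints()] on the columns.
#' @param gain_min Minimum adjusted-R^2 gain to accept a candidate.
#' @param p_drop Significance threshold for post-selection removal.
#' @param vif_max Maximum tolerated variance inflation factor.
#' @return An object of class `"slr_lur"`: selected predictor names (in
#'   selection order), coefficients, constraints, thresholds, fit statistics
#'   and the underlying `lm` fit.
#' @export
fit_slr <- function(X, y, constraints = NULL, gain_min = 0.01,
                    p_drop = 0.10, vif_max = 3) {
  X <- as.data.frame(X)
  X <- X[vapply(X, is.numeric, logical(1))]
  if (nrow(X) < 10) stop("fit_slr: need >= 10 rows")
  if (!all(vapply(X, function(c) all(is.finite(c)), logical(1))))
    stop("fit_slr: non-finite predictor values")
  if (length(y) != nrow(X)) stop("fit_slr: length(y) != nrow(X)")
  if (is.null(constraints)) constraints <- default_sign_constraints(names(X))
  candidates <- sort(names(X))
  # constant columns can never be selected
  candidates <- candidates[vapply(X[candidates], function(c) stats::var(c) > 0,
                                  logical(1))]
  dat <- data.frame(.y = y, X, check.names = FALSE)

  refit <- function(vars) {
    if (!length(vars)) return(stats::lm(.y ~ 1, data = dat))
    fml <- stats::reformulate(sprintf("`%s`", vars), response = ".y")
    stats::lm(fml, data = dat)
  }

  selected <- character()
  cur_adj <- 0
  adj_path <- numeric()
  repeat {
    best <- NULL; best_gain <- -Inf
    for (cand in setdiff(candidates, selected)) {
      trial <- c(selected, cand)
      fit <- refit(trial)
      beta <- stats::coef(fit)[-1]
      if (anyNA(beta)) next
      names(beta) <- trial
      if (!.sign_ok(beta[[cand]], constraints[[cand]] %||% "any")) next
      if (!all(mapply(.sign_ok, beta[selected],
                      constraints[selected] %||% "any"))) next
      if (length(trial) >= 2 &&
          any(.vif(as.matrix(X[trial])) > vif_max)) next
      gain <- summary(fit)$adj.r.squared - cur_adj
      if (gain > best_gain + 1e-12) { best <- cand; best_gain <- gain }
    }
    if (is.null(best) || best_gain < gain_min) break
    selected <- c(selected, best)
    cur_adj <- cur_adj + best_gain
    adj_path <- c(adj_path, cur_adj)
  }

  if (!length(selected))
    warning("no candidate passed at step 1; returning intercept-only model")

  # backward pruning on significance
  repeat {
    fit <- refit(selected)
    if (!length(selected)) break
    p <- summary(fit)$coefficients[-1, 4]
    names(p) <- selected
    worst <- names(which.max(p))
    if (p[[worst]] > p_drop) selected <- setdiff(selected, worst) else break
  }
  fit <- refit(selected)
  beta <- stats::coef(fit)
  names(beta) <- c("(Intercept)", selected)

  structure(list(selected = selected,
                 coefficients = beta,
                 sign_constraints = constraints,
                 thresholds = list(gain_min = gain_min, p_drop = p_drop,
                                   vif_max = vif_max),
                 fit_stats = list(adj_r2 = summary(fit)$adj.r.squared,
                                  r2 = summary(fit)$r.squared,
                                  n = nrow(X)),
                 adj_r2_path = adj_path,
                 fit = fit),
            class = "slr_lur")
}

#' Predict from a stepwise LUR model
#'
#' Plain linear prediction (no clipping); applied to another city's feature
#' table this is the "directly applied" baseline, extrapolating linearly
#' outside the training covariate range.
#'
#' @param object An `"slr_lur"` model.
#' @param newdata Data.frame containing all selected predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.slr_lur <- function(object, newdata, ...) {
  miss <- setdiff(object$selected, names(newdata))
  if (length(miss))
    stop("predict.slr_lur: missing column(s): ", paste(miss, collapse = ", "))
  b <- object$coefficients
  out <- rep(b[["(Intercept)"]], nrow(newdata))
  for (v in object$selected) out <- out + b[[v]] * newdata[[v]]
  out
}

#' @export
coef.slr_lur <- function(object, ...) object$coefficients

#' @export
print.slr_lur <- function(x, ...) {
  cat("Stepwise LUR model\n")
  cat(sprintf("  n = %d, adjusted R2 = %.3f\n", x$fit_stats$n, x$fit_stats$adj_r2))
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  } else cat("  intercept-only\n")
  invisible(x)
}

#' @export
summary.slr_lur <- function(object, ...) summary(object$fit)

#' @export
residuals.slr_lur <- function(object, ...) stats::residuals(object$fit)

#' Serialize a stepwise LUR model to JSON
#'
#' @param model An `"slr_lur"` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
slr_to_json <- function(model, path) {
  jsonlite::write_json(list(selected = model$selected,
                            coefficients = as.list(model$coefficients),
                            sign_constraints = as.list(model$sign_constraints),
                            thresholds = model$thresholds,
                            fit_stats = model$fit_stats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stepwise LUR model from JSON
#'
#' @param path Path written by [slr_to_json()].
#' @return An `"slr_lur"` model (without the underlying `lm` fit).
#' @export
slr_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected = as.character(o$selected),
                 coefficients = unlist(o$coefficients),
                 sign_constraints = unlist(o$sign_constraints),
                 thresholds = o$thresholds,
                 fit_stats = o$fit_stats,
                 fit = NULL),
            class = "slr_lur")
}

#' Learning curve of the local reference model over collection days
#'
#' For each number of days `D` in `days_grid`, `n_resamples` random
#' subsamples of `D` distinct drive days are drawn without replacement; the
#' per-segment aggregates are rebuilt from only those days, a stepwise LUR is
#' fitted, and its predictions are evaluated at the validation sites.
#'
#' @param features Feature table (data.frame with `segment_id`).
#' @param readings Snapped readings with `segment_id`, `drive_day`, `value`.
#' @param days_grid Integer vector of day counts.
#' @param eval_features Feature table rows for the validation sites.
#' @param eval_obs Observed long-term values at the validation sites.
#' @param n_resamples Resamples per day count (default 20).
#' @param seed Integer seed for the day sampler.
#' @param ... Passed to [fit_slr()].
#' @return Data.frame with columns `days`, `resample`, `r2`, `mae`, `rmse`
#'   (`length(days_grid) * n_resamples` rows).
#' @export
learning_curve <- function(features, readings, days_grid, eval_features,
                           eval_obs, n_resamples = 20, seed = 1, ...) {
  all_days <- sort(unique(readings$drive_day))
  if (any(days_grid > length(all_days)))
    stop("days_grid exceeds available drive days (", length(all_days), ")")
  set.seed(seed)
  rows <- vector("list", length(days_grid) * n_resamples)
  k <- 0L
  for (D in days_grid) {
    for (b in seq_len(n_resamples)) {
      days <- sample(all_days, D)
      sub <- readings[readings$drive_day %in% days, , drop = FALSE]
      agg <- mean_of_means(sub)
      idx <- match(agg$segment_id, features$segment_id)
      ok <- !is.na(idx)
      Xfit <- features[idx[ok], setdiff(names(features), "segment_id"),
                       drop = FALSE]
      model <- fit_slr(Xfit, agg$value[ok], ...)
      ev <- suppressWarnings(evaluate(predict(model, eval_features), eval_obs))
      k <- k + 1L
      rows[[k]] <- data.frame(days = D, resample = b, r2 = ev$r2,
                              mae = ev$mae, rmse = ev$rmse)
    }
  }
  do.call(rbind, rows)
}
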