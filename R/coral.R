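# CORrelation ALignment (CORAL) for unsupervised cross-city transfer of LUR
# models. Stage 1 linearly transforms the source feature space so that its
# covariance matches the target city's feature covariance (whitening by the
# source covariance, recoloring by the target covariance). Stage 2 fits a
# ridge regression of the source concentrations on the aligned source
# features; target predictions then come from target features directly,
# which already live in the target-shaped space. No target concentration
# enters the fit at any point: the alignment corrects covariate shift only,
# not conditional shift.

#' Regularized sample covariance of a feature matrix
#'
#' Column-centered sample covariance (denominator n - 1) plus
#' `lambda_reg` on the diagonal. Feature tables with many all-zero buffer
#' columns are rank deficient; the ridge on the diagonal keeps the
#' matrix square roots well defined.
#'
#' @param X Numeric matrix with n >= 2 rows.
#' @param lambda_reg Non-negative diagonal regularizer.
#' @return d x d covariance matrix.
#' @export
estimate_covariance <- function(X, lambda_reg = 0) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("estimate_covariance: need >= 2 rows")
  stats::cov(X) + diag(lambda_reg, ncol(X))
}

# Symmetric matrix power via eigendecomposition, eigenvalues clipped below.
.sym_power <- function(M, p, clip = 0) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, clip)
  e$vectors %*% (vals^p * t(e$vectors))
}

#' Closed-form CORAL alignment transform
#'
#' Returns `A = C_S^{-1/2} C_T^{1/2}` (symmetric matrix square roots via
#' eigendecomposition), the minimizer of the Frobenius alignment objective
#' `|| A' C_S A - C_T ||_F^2`; at the returned `A` the objective is 0 up to
#' numerical error, so transformed source features have exactly the target
#' covariance.
#'
#' @param C_S,C_T Symmetric positive-definite covariance matrices
#'   (regularize with [estimate_covariance()] if near singular).
#' @param clip Lower clip applied to eigenvalues before taking powers.
#' @return d x d transform matrix `A`.
#' @export
coral_transform <- function(C_S, C_T, clip = 0) {
  if (!isSymmetric(unname(C_S), tol = 1e-8) ||
      !isSymmetric(unname(C_T), tol = 1e-8))
    stop("coral_transform: covariance matrices must be symmetric")
  .sym_power(C_S, -0.5, clip) %*% .sym_power(C_T, 0.5, clip)
}

#' Frobenius alignment objective
#'
#' `|| A' C_S A - C_T ||_F^2`, the quantity the CORAL transform minimizes.
#'
#' @param A Candidate transform.
#' @param C_S,C_T Covariance matrices.
#' @return Scalar objective value.
#' @export
coral_objective <- function(A, C_S, C_T) {
  D <- t(A) %*% C_S %*% A - C_T
  sum(D * D)
}

# Closed-form ridge on a standardized design: returns intercept-free
# coefficients for the standardized columns plus the response mean.
.ridge_fit <- function(Z, y, alpha) {
  d <- ncol(Z)
  G <- crossprod(Z) + diag(alpha, d)
  drop(solve(G, crossprod(Z, y - mean(y))))
}

.ridge_cv_alpha <- function(Z, y, alphas, nfolds = 5, seed = 1) {
  n <- nrow(Z)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(nfolds), n))
  err <- vapply(alphas, function(a) {
    se <- 0
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      b <- .ridge_fit(Z[tr, , drop = FALSE], y[tr], a)
      pred <- mean(y[tr]) + Z[!tr, , drop = FALSE] %*% b
      se <- se + sum((y[!tr] - pred)^2)
    }
    se
  }, numeric(1))
  alphas[which.min(err)]
}

#' Fit a CORAL-aligned ridge LUR model for one source-target city pair
#'
#' Both feature tables are mean-centered per domain (the alignment is a pure
#' covariance statement; per-domain centering removes the mean shift as
#' well). The alignment transform is computed from the regularized source
#' and target covariances, the centered source features are pushed through
#' it, standardized, and a ridge regression of the source response on the
#' aligned features is fitted. Target labels are never consumed.
#'
#' @param X_s Source feature table (data.frame/matrix; a `segment_id`
#'   column, if present, is dropped).
#' @param y_s Source per-segment response (mean-of-means concentrations).
#' @param X_t Target feature table with identical columns.
#' @param lambda_reg Covariance regularizer; default `1e-5` times the mean
#'   pooled diagonal variance (relative regularization).
#' @param ridge_alpha Ridge penalty on the standardized aligned features
#'   (default 1), or `"cv"` to choose from a log-spaced grid by 5-fold
#'   cross-validation on the source.
#' @return An object of class `"coral_lur"` storing the transform, centering
#'   and scaling constants, and ridge coefficients.
#' @export
coral_lur <- function(X_s, y_s, X_t, lambda_reg = NULL, ridge_alpha = 1) {
  drop_id <- function(X) {
    X <- as.data.frame(X)
    as.matrix(X[setdiff(names(X), "segment_id")])
  }
  X_s <- drop_id(X_s); X_t <- drop_id(X_t)
  if (!identical(colnames(X_s), colnames(X_t))) {
    d1 <- setdiff(colnames(X_s), colnames(X_t))
    d2 <- setdiff(colnames(X_t), colnames(X_s))
    if (length(d1) || length(d2) ||
        !setequal(colnames(X_s), colnames(X_t)))
      stop("coral_lur: column mismatch between source and target",
           if (length(d1)) paste0("; source-only: ", paste(d1, collapse = ", ")),
           if (length(d2)) paste0("; target-only: ", paste(d2, collapse = ", ")))
    X_t <- X_t[, colnames(X_s), drop = FALSE]
  }
  if (length(y_s) != nrow(X_s)) stop("coral_lur: length(y_s) != nrow(X_s)")

  mu_s <- colMeans(X_s)
  mu_t <- colMeans(X_t)
  Xs_c <- sweep(X_s, 2, mu_s)
  Xt_c <- sweep(X_t, 2, mu_t)
  if (is.null(lambda_reg)) {
    base_var <- mean(c(diag(stats::cov(Xs_c)), diag(stats::cov(Xt_c))))
    lambda_reg <- 1e-5 * max(base_var, .Machine$double.eps)
  }
  C_S <- estimate_covariance(Xs_c, lambda_reg)
  C_T <- estimate_covariance(Xt_c, lambda_reg)
  A <- coral_transform(C_S, C_T, clip = lambda_reg)

  Xs_al <- Xs_c %*% A
  scale_ <- apply(Xs_al, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Z <- sweep(Xs_al, 2, scale_, "/")
  if (identical(ridge_alpha, "cv"))
    ridge_alpha <- .ridge_cv_alpha(Z, y_s, alphas = 10^seq(-2, 3))
  beta <- .ridge_fit(Z, y_s, ridge_alpha)

  structure(list(A = A,
                 columns = colnames(X_s),
                 lambda_reg = lambda_reg,
                 ridge_alpha = ridge_alpha,
                 source_means = mu_s,
                 target_means = mu_t,
                 scale = scale_,
                 ridge_coefficients = c("(Intercept)" = mean(y_s),
                                        stats::setNames(beta, colnames(X_s))),
                 n_source = nrow(X_s),
                 n_target = nrow(X_t)),
            class = "coral_lur")
}

#' Predict target concentrations from a CORAL LUR model
#'
#' Target features are centered by the stored target means and scaled by the
#' stored standardization; no alignment is applied at prediction time
#' because centered target features already have the covariance the ridge
#' was trained under. Deterministic: repeated calls are bitwise identical.
#'
#' @param object A `"coral_lur"` model.
#' @param newdata Target feature table containing all model columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.coral_lur <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$columns, names(newdata))
  if (length(miss))
    stop("predict.coral_lur: missing column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[object$columns])
  Z <- sweep(sweep(X, 2, object$target_means), 2, object$scale, "/")
  b <- object$ridge_coefficients
  drop(b[["(Intercept)"]] + Z %*% b[-1])
}

#' @export
coef.coral_lur <- function(object, ...) object$ridge_coefficients

#' @export
print.coral_lur <- function(x, ...) {
  cat("CORAL-aligned ridge LUR model\n")
  cat(sprintf("  %d predictors, n_source = %d, n_target = %d\n",
              length(x$columns), x$n_source, x$n_target))
  cat(sprintf("  lambda_reg = %.3g, ridge_alpha = %.3g\n",
              x$lambda_reg, x$ridge_alpha))
  invisible(x)
}

#' Serialize a CORAL LUR model to JSON
#'
#' The transform is stored row-major along with means, scales, ridge terms
#' and column names.
#'
#' @param model A `"coral_lur"` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
coral_to_json <- function(model, path) {
  jsonlite::write_json(list(columns = model$columns,
                            A = as.vector(t(model$A)),
                            lambda_reg = model$lambda_reg,
                            ridge_alpha = model$ridge_alpha,
                            source_means = as.list(model$source_means),
                            target_means = as.list(model$target_means),
                            scale = as.list(model$scale),
                            ridge_coefficients = as.list(model$ridge_coefficients),
                            n_source = model$n_source,
                            n_target = model$n_target),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CORAL LUR model from JSON
#'
#' @param path Path written by [coral_to_json()].
#' @return A `"coral_lur"` model.
#' @export
coral_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(o$columns)
  structure(list(A = matrix(o$A, d, d, byrow = TRUE),
                 columns = as.character(o$columns),
                 lambda_reg = o$lambda_reg,
                 ridge_alpha = o$ridge_alpha,
                 source_means = unlist(o$source_means),
                 target_means = unlist(o$target_means),
                 scale = unlist(o$scale),
                 ridge_coefficients = unlist(o$ridge_coefficients),
                 n_source = o$n_source,
                 n_target = o$n_target),
            class = "coral_lur")
}
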