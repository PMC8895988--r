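## Ridge-regression BLUP, predictor-agnostic: REML estimation of the single
## variance ratio lambda = Ve/Vu by spectral decomposition of the predictor
## kernel, marker/wavelength effect estimation, prediction of unobserved
## genotypes, and the algebraically equivalent kernel (GBLUP) path used as
## an internal correctness oracle.
##
## Model: y = X beta + Z u + eps, u ~ iid N(0, Vu), eps ~ N(0, Ve I), so
## Var(y) = Vu (Z Z' + lambda I). The restricted likelihood is profiled in
## lambda on the eigenvalues of S K S (S the projection orthogonal to X),
## then maximized by Brent's method on log(lambda).

.rr_eigen <- function(y, Z, X) {
  n <- length(y)
  q <- ncol(X)
  K <- tcrossprod(Z)
  XtXi <- solve(crossprod(X))
  S <- diag(n) - X %*% XtXi %*% t(X)
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  keep <- seq_len(n - q)            # the q trailing eigenvalues are ~0 by construction
  theta <- pmax(es$values[keep], 0)
  # project y through S before rotating: when K is rank-deficient the
  # zero-eigenvalue block mixes the X directions with genuine kernel-null
  # directions, and unprojected y would leak its fixed-effect component in
  eta <- drop(crossprod(es$vectors[, keep, drop = FALSE], S %*% y))
  list(K = K, theta = theta, eta = eta, n = n, q = q)
}

#' Profiled restricted log-likelihood of the ridge variance ratio
#'
#' Returns a function of log(lambda) evaluating the REML log-likelihood of
#' the single-ratio ridge model (up to an additive constant), suitable for
#' grid evaluation or optimization.
#'
#' @param y response vector (one value per training genotype)
#' @param Z genotypes x predictors matrix
#' @param X fixed-effect design matrix (default: intercept only)
#' @return function(log_lambda) -> restricted log-likelihood
#' @export
rr_profile_reml <- function(y, Z, X = NULL) {
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, length(y), 1)
  prep <- .rr_eigen(y, Z, X)
  df <- prep$n - prep$q
  function(log_lambda) {
    lam <- exp(log_lambda)
    d <- prep$theta + lam
    ss <- sum(prep$eta^2 / d)
    0.5 * (df * log(df / (2 * pi)) - df - df * log(ss) - sum(log(d)))
  }
}

#' Fit a ridge-regression BLUP model
#'
#' Estimates the variance components (Vu, Ve) by REML of the single ratio
#' lambda = Ve/Vu (Brent search on log lambda in [1e-5, 1e5] after one
#' eigendecomposition), then the fixed effects by GLS and the predictor
#' effects by u = Z' H^-1 (y - X beta) with H = Z Z' + lambda I. Applies
#' identically to marker dosages and standardized spectral predictors.
#'
#' @param y named response vector (typically per-genotype BLUEs)
#' @param Z genotypes x predictors matrix (no missing values); rows matched
#'   to `y` by name when both are named
#' @param lambda optional fixed variance ratio (skips REML)
#' @param bounds log-lambda search interval
#' @return an `rr_model`: list with beta (intercept), u (named predictor
#'   effects), Vu, Ve, lambda, loglik, feature_ids, train_ids
#' @export
solve_rrblup <- function(y, Z, lambda = NULL, bounds = c(1e-5, 1e5)) {
  Z <- as.matrix(Z)
  if (!is.null(names(y)) && !is.null(rownames(Z))) {
    if (!all(names(y) %in% rownames(Z))) {
      stop("y contains genotypes absent from Z", call. = FALSE)
    }
    Z <- Z[names(y), , drop = FALSE]
  }
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(Z) == n, n >= 2, !anyNA(Z))
  feature_ids <- colnames(Z) %||% paste0("f", seq_len(ncol(Z)))
  if (stats::var(y) == 0) {
    warning("no signal: response has zero variance; returning boundary model")
    return(structure(list(beta = y[1], u = stats::setNames(rep(0, ncol(Z)), feature_ids),
                          Vu = 0, Ve = 0, lambda = Inf, loglik = NA_real_,
                          feature_ids = feature_ids,
                          train_ids = rownames(Z)), class = "rr_model"))
  }
  X <- matrix(1, n, 1)
  obj <- rr_profile_reml(y, Z, X)
  if (is.null(lambda)) {
    opt <- stats::optimize(obj, interval = log(bounds), maximum = TRUE,
                           tol = 1e-9)
    lambda <- exp(opt$maximum)
    loglik <- opt$objective
  } else {
    loglik <- obj(log(lambda))
  }
  if (!is.finite(loglik)) {
    stop(sprintf("numerical error: non-finite restricted likelihood at lambda=%g",
                 lambda), call. = FALSE)
  }
  K <- tcrossprod(Z)
  H <- K + diag(lambda, n)
  Hi_y <- solve(H, y)
  Hi_X <- solve(H, X)
  beta <- drop(solve(crossprod(X, Hi_X), crossprod(X, Hi_y)))
  e <- y - X %*% beta
  Hi_e <- solve(H, e)
  u <- drop(crossprod(Z, Hi_e))
  prep <- .rr_eigen(y, Z, X)
  Vu <- sum(prep$eta^2 / (prep$theta + lambda)) / (prep$n - prep$q)
  structure(list(beta = beta, u = stats::setNames(u, feature_ids),
                 Vu = Vu, Ve = lambda * Vu, lambda = lambda, loglik = loglik,
                 feature_ids = feature_ids, train_ids = rownames(Z)),
            class = "rr_model")
}

#' @export
print.rr_model <- function(x, ...) {
  cat(sprintf("<rr_model> %d predictors, lambda=%.4g (Vu=%.4g, Ve=%.4g)\n",
              length(x$u), x$lambda, x$Vu, x$Ve))
  invisible(x)
}

#' Predict genotypes from a fitted ridge model
#'
#' yhat = beta0 + Z_new u. The columns of `Z_new` must match the model's
#' feature ids exactly in identity and order.
#'
#' @param model an `rr_model`
#' @param Z_new genotypes x predictors matrix
#' @return named numeric vector of predictions
#' @export
predict_new <- function(model, Z_new) {
  Z_new <- as.matrix(Z_new)
  ids <- colnames(Z_new) %||% paste0("f", seq_len(ncol(Z_new)))
  if (!identical(ids, model$feature_ids)) {
    missing_f <- setdiff(model$feature_ids, ids)
    extra_f <- setdiff(ids, model$feature_ids)
    stop(sprintf("feature mismatch: %d missing (%s), %d extra (%s)%s",
                 length(missing_f), paste(utils::head(missing_f, 3), collapse = ","),
                 length(extra_f), paste(utils::head(extra_f, 3), collapse = ","),
                 if (!length(missing_f) && !length(extra_f)) "; column order differs" else ""),
         call. = FALSE)
  }
  stats::setNames(drop(model$beta + Z_new %*% model$u),
                  rownames(Z_new))
}

#' Kernel (GBLUP) predictions equivalent to the ridge model
#'
#' Fits the genotype-level model g ~ N(0, Vg K), K = Z Z', with the same
#' profiled REML, and predicts via covariances K_new = Z_new Z'. Predictions
#' are algebraically identical to the marker-effect path and serve as its
#' numerical oracle; if K is numerically indefinite a diagonal jitter is
#' added and logged via a message.
#'
#' @param y training response
#' @param Z training predictor matrix
#' @param Z_new prediction predictor matrix (default: the training matrix,
#'   giving fitted values)
#' @param lambda optional fixed variance ratio
#' @return named numeric vector of kernel-path predictions
#' @export
gblup_equiv <- function(y, Z, Z_new = Z, lambda = NULL) {
  Z <- as.matrix(Z); Z_new <- as.matrix(Z_new)
  if (!is.null(names(y)) && !is.null(rownames(Z))) Z <- Z[names(y), , drop = FALSE]
  y <- as.numeric(y)
  n <- length(y)
  X <- matrix(1, n, 1)
  if (is.null(lambda)) {
    obj <- rr_profile_reml(y, Z, X)
    lambda <- exp(stats::optimize(obj, interval = log(c(1e-5, 1e5)),
                                  maximum = TRUE, tol = 1e-9)$maximum)
  }
  K <- tcrossprod(Z)
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(abs(K))) {
    message("kernel numerically indefinite; adding diagonal jitter")
    K <- K + diag(1e-8 * mean(diag(K)), n)
  }
  H <- K + diag(lambda, n)
  Hi_X <- solve(H, X)
  Hi_y <- solve(H, y)
  beta <- drop(solve(crossprod(X, Hi_X), crossprod(X, Hi_y)))
  e <- y - X %*% beta
  K_new <- tcrossprod(Z_new, Z)
  stats::setNames(drop(beta + K_new %*% solve(H, e)), rownames(Z_new))
}
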