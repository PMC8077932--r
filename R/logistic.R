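# L2-penalized logistic regression by iteratively reweighted least squares.
# This is the optimizer behind both the propensity model and the intake
# classifier; it is written out (rather than delegated to glm/glmnet) because
# the fitting procedure itself is part of the package's contract and is
# cross-checked against an independent Newton oracle in the tests.

#' Fit an L2-penalized logistic regression by IRLS
#'
#' Maximizes the penalized Bernoulli log-likelihood
#' `sum(y * log p + (1 - y) * log(1 - p)) - lambda/2 * sum(beta_j^2)`
#' (intercept unpenalized) by iteratively reweighted least squares, which for
#' this model is exactly Newton's method. Features are standardized to zero
#' mean and unit variance internally; constant features are dropped with a
#' warning. Deterministic.
#'
#' @param x Numeric matrix (rows = observations, named columns).
#' @param y 0/1 (or logical) response.
#' @param lambda L2 penalty on standardized coefficients (default 1).
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @param standardize Standardize columns internally (default TRUE).
#' @return List of class `pv_logistic` with standardized-scale coefficients
#'   (`coef_std`), the equivalent raw-scale coefficients (`coefficients`,
#'   `intercept`), the feature order, the centering/scaling used, and a
#'   `convergence` record (`iterations`, `grad_norm`).
#' @export
fit_logistic_irls <- function(x, y, lambda = 1, tol = 1e-8, max_iter = 100L,
                              standardize = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  pv_assert(nrow(x) == length(y), "x and y sizes differ")
  pv_assert(all(y %in% c(0, 1)), "y must be binary")
  if (length(unique(y)) < 2L)
    pv_stop("response has a single class; cannot fit a classifier",
            "pv_degenerate_error")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(utils::head(colnames(x)[const], 5L), collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  p <- ncol(x)
  centers <- if (standardize) colMeans(x) else rep(0, p)
  scales <- if (standardize) sds else rep(1, p)
  xs <- sweep(sweep(x, 2L, centers, "-"), 2L, scales, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  pen <- c(0, rep(lambda, p))

  beta <- rep(0, p + 1L)
  grad_norm <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    delta <- solve(H, grad)
    beta <- beta + delta
    grad_norm <- max(abs(grad))
    if (max(abs(delta)) < tol) { converged <- TRUE; iterations <- it; break }
  }
  if (!converged)
    pv_stop(sprintf("IRLS did not converge in %d iterations (|grad| = %.3e)",
                    max_iter, grad_norm),
            "pv_convergence_error",
            data = list(iterations = max_iter, grad_norm = grad_norm,
                        beta = beta))
  coef_std <- stats::setNames(beta, colnames(X))
  beta_raw <- beta[-1L] / scales
  intercept_raw <- unname(beta[1L]) - sum(beta[-1L] * centers / scales)
  structure(list(coef_std = coef_std,
                 coefficients = stats::setNames(beta_raw, colnames(x)),
                 intercept = intercept_raw,
                 feature_order = colnames(x),
                 centers = centers, scales = scales, lambda = lambda,
                 convergence = list(iterations = iterations,
                                    grad_norm = grad_norm)),
            class = "pv_logistic")
}

#' Predicted probabilities from a fitted logistic model
#'
#' @param model A `pv_logistic`.
#' @param x Numeric matrix with (at least) the model's feature columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_logistic <- function(model, x) {
  x <- as.matrix(x)
  missing <- setdiff(model$feature_order, colnames(x))
  pv_assert(length(missing) == 0L,
            sprintf("missing feature(s): %s", paste(utils::head(missing, 5L),
                                                    collapse = ", ")))
  x <- x[, model$feature_order, drop = FALSE]
  stats::plogis(model$intercept + drop(x %*% model$coefficients))
}

#' @export
print.pv_logistic <- function(x, ...) {
  cat(sprintf("<pv_logistic> %d features, lambda = %g, converged in %d iterations (|grad| = %.2e)\n",
              length(x$feature_order), x$lambda, x$convergence$iterations,
              x$convergence$grad_norm))
  invisible(x)
}
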