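# independent Newton optimizer for the same penalized objective, written
# against the maths rather than the package implementation
newton_logistic_oracle <- function(x, y, lambda, max_iter = 200L) {
  xs <- scale(x)
  X <- cbind(1, xs)
  pen <- c(0, rep(lambda, ncol(xs)))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    g <- drop(t(X) %*% (y - mu)) - pen * beta
    H <- t(X) %*% (X * (mu * (1 - mu))) + diag(pen)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

test_that("IRLS coefficients match an independent Newton oracle to 1e-6", {
  set.seed(77)
  x <- matrix(rnorm(30), nrow = 10, ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0)
  fit <- fit_logistic_irls(x, y, lambda = 1)
  oracle <- newton_logistic_oracle(x, y, lambda = 1)
  expect_lt(max(abs(unname(fit$coef_std) - oracle)), 1e-6)
})

test_that("a symmetric two-point design gives zero intercept and score 0.5 at the midpoint", {
  x <- matrix(c(-1, -1, 1, 1), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 1, 1)
  fit <- fit_logistic_irls(x, y, lambda = 1)
  expect_lt(abs(fit$coef_std[["(Intercept)"]]), 1e-8)
  expect_equal(unname(predict_logistic(fit, matrix(0, 1, 1,
                                                   dimnames = list(NULL, "f")))),
               0.5, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected and constant features dropped", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_logistic_irls(x, rep(1, 10)), class = "pv_degenerate_error")
  x2 <- cbind(x, cst = 1)
  expect_warning(fit <- fit_logistic_irls(x2, rep(c(0, 1), 5)), "constant")
  expect_false("cst" %in% fit$feature_order)
})

test_that("propensity scores are invariant to affine feature rescaling", {
  set.seed(42)
  n <- 200
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  y <- rbinom(n, 1, stats::plogis(0.8 * x[, 1]))
  rownames(x) <- paste0("u", seq_len(n))
  m1 <- fit_propensity(x, stats::setNames(y, rownames(x)))
  x2 <- x; x2[, 1] <- 3 * x2[, 1] + 7
  m2 <- fit_propensity(x2, stats::setNames(y, rownames(x2)))
  expect_equal(predict_propensity(m1, x), predict_propensity(m2, x2),
               tolerance = 1e-6)
})

test_that("stratification matches a brute-force binning oracle and boundary rules", {
  expect_error(stratify(c(u1 = 0.5), c(u1 = TRUE), n_strata = 1),
               class = "pv_argument_error")
  set.seed(13)
  n <- 1000
  scores <- stats::setNames(runif(n), paste0("u", 1:n))
  scores[1:2] <- c(0.005, 1.0)
  trt <- stats::setNames(rep(c(TRUE, FALSE), n / 2), names(scores))
  co <- stratify(scores, trt, n_strata = 100)
  expect_equal(co$assignment$stratum[1], 0L)
  expect_equal(co$assignment$stratum[2], 99L)
  oracle <- pmin(floor(unname(scores) * 100), 99L)
  expect_equal(co$assignment$stratum, as.integer(oracle))
  # sum of stratum sizes equals the number of users
  expect_equal(sum(co$strata$n_treatment + co$strata$n_control), n)
  expect_equal(nrow(co$strata), 100L)
  expect_equal(co$strata$hi - co$strata$lo, rep(0.01, 100))
  # every user sits in exactly one stratum covering its score
  lo <- co$strata$lo[match(co$assignment$stratum, co$strata$stratum)]
  hi <- co$strata$hi[match(co$assignment$stratum, co$strata$stratum)]
  expect_true(all(co$assignment$score >= lo &
                  (co$assignment$score < hi | co$assignment$score == 1)))
})

test_that("stratum retention respects min_per_arm", {
  scores <- c(a = 0.05, b = 0.05, c = 0.05, d = 0.55)
  trt <- c(a = TRUE, b = FALSE, c = FALSE, d = TRUE)
  co <- stratify(scores, trt, n_strata = 10, min_per_arm = 1)
  expect_true(co$strata$retained[co$strata$stratum == 0])
  expect_false(co$strata$retained[co$strata$stratum == 5])  # no control
  co2 <- stratify(scores, trt, n_strata = 10, min_per_arm = 2)
  expect_false(any(co2$strata$retained))
})

test_that("balance diagnostics: identical distributions, zero-SD flags, single stratum", {
  set.seed(19)
  n <- 120
  x <- cbind(f = rnorm(n), cst = 1)
  rownames(x) <- paste0("u", 1:n)
  trt <- stats::setNames(rep(c(TRUE, FALSE), n / 2), rownames(x))
  # one stratum holding everyone: after equals before by construction
  sc <- stats::setNames(rep(0.5, n), rownames(x))
  co <- stratify(sc, trt, n_strata = 2)
  bal <- balance_diagnostics(co, x)
  expect_equal(bal$smd_after[bal$covariate == "f"],
               bal$smd_before[bal$covariate == "f"])
  expect_true(bal$zero_sd[bal$covariate == "cst"])
  expect_equal(bal$smd_before[bal$covariate == "cst"], 0)
  # identical treated/control values -> SMD 0
  x2 <- cbind(f = rep(c(1, 2), n / 2))
  rownames(x2) <- rownames(x)
  bal2 <- balance_diagnostics(co, x2)
  expect_lt(bal2$smd_before[1], 0.2)
})

test_that("stratifying on a fitted propensity score reduces confounder imbalance", {
  wins <- 0L
  for (r in 1:5) {
    set.seed(860 + r)
    n <- 800
    z <- rnorm(n)
    x <- cbind(conf = z + rnorm(n, 0, 0.4), noise = rnorm(n))
    rownames(x) <- paste0("u", 1:n)
    y <- stats::setNames(rbinom(n, 1, stats::plogis(1.2 * z)) == 1, rownames(x))
    m <- fit_propensity(x, y)
    co <- stratify(predict_propensity(m, x), y, n_strata = 100)
    bal <- balance_diagnostics(co, x)
    row <- bal[bal$covariate == "conf", ]
    wins <- wins + (row$smd_after < row$smd_before)
  }
  expect_gte(wins, 4L)
})
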