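#' Fit a propensity model
#'
#' Logistic regression of treatment status on the pretreatment covariates,
#' fitted by L2-penalized IRLS ([fit_logistic_irls()]). The default penalty
#' of 1 on standardized features keeps the high-dimensional unigram block
#' well-conditioned.
#'
#' @param covariates Data frame from [covariate_table()] (a `user_id` column
#'   plus numeric features) or a numeric matrix with rownames as user ids.
#' @param treatment Named logical/0-1 vector (user -> treated) or unnamed
#'   vector aligned with the covariate rows.
#' @param l2_penalty L2 penalty (default 1).
#' @param tol,max_iter Passed to the optimizer.
#' @return A `pv_propensity` model wrapping the `pv_logistic` fit.
#' @export
fit_propensity <- function(covariates, treatment, l2_penalty = 1,
                           tol = 1e-8, max_iter = 100L) {
  xm <- covariate_matrix(covariates)
  if (!is.null(names(treatment))) treatment <- treatment[rownames(xm)]
  pv_assert(!anyNA(treatment), "treatment labels missing for some users")
  fit <- fit_logistic_irls(xm, as.numeric(treatment), lambda = l2_penalty,
                           tol = tol, max_iter = max_iter)
  structure(list(fit = fit, feature_order = fit$feature_order),
            class = "pv_propensity")
}

# normalize covariate containers to a numeric matrix with user-id rownames
covariate_matrix <- function(covariates) {
  if (is.matrix(covariates)) return(covariates)
  stopifnot(is.data.frame(covariates))
  ids <- covariates$user_id
  xm <- as.matrix(covariates[, setdiff(names(covariates), "user_id"),
                             drop = FALSE])
  storage.mode(xm) <- "double"
  rownames(xm) <- ids
  xm
}

#' Propensity scores for users
#'
#' @param model A `pv_propensity`.
#' @param covariates Covariate table or matrix (see [fit_propensity()]).
#' @return Named numeric vector of scores in (0, 1), names = user ids.
#' @export
predict_propensity <- function(model, covariates) {
  xm <- covariate_matrix(covariates)
  stats::setNames(predict_logistic(model$fit, xm), rownames(xm))
}

#' Stratify propensity scores into equal-width bins
#'
#' Partitions `[0, 1)` into `n_strata` equal-width intervals (the last bin
#' closed at 1; left-closed, right-open elsewhere), assigns every user to the
#' bin containing its score, and retains strata with at least `min_per_arm`
#' users in each arm. Dropped strata are recorded, not silently discarded.
#'
#' @param scores Named numeric vector of propensity scores in `[0, 1]`.
#' @param treatment Named logical vector (user -> treated).
#' @param n_strata Number of equal-width bins (default 100).
#' @param min_per_arm Minimum users per arm for a stratum to be retained.
#' @return A list of class `pv_cohort`: `assignment` (user, arm, score,
#'   stratum index, retained flag), `strata` (per-bin summary over all
#'   `n_strata` bins, with `lo`, `hi`, arm counts and retention flag), and
#'   `n_strata`. Stratum indices are 0-based.
#' @export
stratify <- function(scores, treatment, n_strata = 100L, min_per_arm = 1L) {
  if (!is.numeric(n_strata) || n_strata < 2L)
    pv_stop("n_strata must be at least 2", "pv_argument_error")
  n_strata <- as.integer(n_strata)
  pv_assert(all(scores >= 0 & scores <= 1), "scores must lie in [0, 1]")
  pv_assert(!is.null(names(scores)), "scores must be named by user id")
  treatment <- treatment[names(scores)]
  pv_assert(!anyNA(treatment), "treatment labels missing for some scored users")

  idx <- pmin(floor(scores * n_strata), n_strata - 1L)
  assignment <- data.frame(user_id = names(scores), score = unname(scores),
                           arm = ifelse(treatment, "treatment", "control"),
                           stratum = as.integer(idx), stringsAsFactors = FALSE)
  bins <- data.frame(stratum = 0:(n_strata - 1L))
  bins$lo <- bins$stratum / n_strata
  bins$hi <- (bins$stratum + 1L) / n_strata
  tab_t <- table(factor(idx[treatment], levels = bins$stratum))
  tab_c <- table(factor(idx[!treatment], levels = bins$stratum))
  bins$n_treatment <- as.integer(tab_t)
  bins$n_control <- as.integer(tab_c)
  bins$retained <- bins$n_treatment >= min_per_arm & bins$n_control >= min_per_arm
  assignment$retained <- bins$retained[match(assignment$stratum, bins$stratum)]
  structure(list(assignment = assignment, strata = bins,
                 n_strata = n_strata, min_per_arm = as.integer(min_per_arm)),
            class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat(sprintf("<pv_cohort> %d strata (%d retained), %d users retained of %d\n",
              x$n_strata, sum(x$strata$retained), sum(x$assignment$retained),
              nrow(x$assignment)))
  invisible(x)
}

smd_pair <- function(xt, xc) {
  if (length(xt) == 0L || length(xc) == 0L) return(c(smd = 0, zero_sd = 1))
  vt <- if (length(xt) > 1L) stats::var(xt) else 0
  vc <- if (length(xc) > 1L) stats::var(xc) else 0
  pooled <- sqrt((vt + vc) / 2)
  if (!is.finite(pooled) || pooled == 0) return(c(smd = 0, zero_sd = 1))
  c(smd = abs(mean(xt) - mean(xc)) / pooled, zero_sd = 0)
}

#' Covariate balance diagnostics
#'
#' Standardized mean differences per covariate, before stratification
#' (|mean_T - mean_C| / pooled SD over all retained users) and after
#' stratification: the absolute value of the stratum-size-weighted mean of
#' the signed within-stratum mean differences, divided by the same overall
#' pooled SD. This is the usual stratification-adjusted difference; signed
#' aggregation lets small-stratum noise cancel instead of accumulating, and
#' the shared denominator keeps before/after on one scale. An SMD of a
#' covariate with zero pooled SD is reported as 0 and flagged.
#'
#' @param cohort A `pv_cohort`.
#' @param covariates Covariate table or matrix.
#' @return Data frame with columns `covariate`, `smd_before`, `smd_after`,
#'   `zero_sd`.
#' @export
balance_diagnostics <- function(cohort, covariates) {
  stopifnot(inherits(cohort, "pv_cohort"))
  xm <- covariate_matrix(covariates)
  asg <- cohort$assignment[cohort$assignment$retained, , drop = FALSE]
  asg <- asg[asg$user_id %in% rownames(xm), , drop = FALSE]
  pv_assert(nrow(asg) > 0L, "no retained users with covariates")
  xm <- xm[asg$user_id, , drop = FALSE]
  trt <- asg$arm == "treatment"
  strata <- split(seq_len(nrow(asg)), asg$stratum)
  w <- vapply(strata, length, integer(1))
  w <- w / sum(w)
  out <- lapply(colnames(xm), function(cv) {
    before <- smd_pair(xm[trt, cv], xm[!trt, cv])
    vt <- if (sum(trt) > 1L) stats::var(xm[trt, cv]) else 0
    vc <- if (sum(!trt) > 1L) stats::var(xm[!trt, cv]) else 0
    pooled_sd <- sqrt((vt + vc) / 2)
    within <- vapply(strata, function(rows) {
      xt <- xm[rows[trt[rows]], cv]; xc <- xm[rows[!trt[rows]], cv]
      if (length(xt) == 0L || length(xc) == 0L) return(0)
      mean(xt) - mean(xc)
    }, numeric(1))
    after <- if (pooled_sd > 0) abs(sum(w * within)) / pooled_sd else 0
    data.frame(covariate = cv, smd_before = before[["smd"]],
               smd_after = after,
               zero_sd = before[["zero_sd"]] == 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
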