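#' Relative treatment effect for one stratum and outcome
#'
#' The arm likelihood is the mean, over the arm's users, of each user's
#' post-window positive-post fraction; the RTE is the treated likelihood
#' divided by the control likelihood. A zero arm likelihood is floored at
#' `1 / (2 * total post-window posts in that arm)` and flagged, so ratios and
#' their logs stay finite.
#'
#' @param treat_rates,control_rates Post-window positive fractions of the
#'   stratum's treated / control users for one outcome.
#' @param treat_posts,control_posts Post-window post counts for the same
#'   users.
#' @return List with `p_treat`, `p_control`, `rte`, `n_treat`, `n_control`,
#'   `floored`.
#' @export
stratum_rte <- function(treat_rates, control_rates, treat_posts,
                        control_posts) {
  treat_rates <- treat_rates[!is.na(treat_rates)]
  control_rates <- control_rates[!is.na(control_rates)]
  if (length(treat_rates) == 0L || length(control_rates) == 0L)
    pv_stop("stratum has an empty arm", "pv_empty_arm_error")
  p_t <- mean(treat_rates)
  p_c <- mean(control_rates)
  floored <- FALSE
  eps_t <- 1 / (2 * max(sum(treat_posts), 1))
  eps_c <- 1 / (2 * max(sum(control_posts), 1))
  if (p_t == 0) { p_t_use <- eps_t; floored <- TRUE } else p_t_use <- p_t
  if (p_c == 0) { p_c_use <- eps_c; floored <- TRUE } else p_c_use <- p_c
  list(p_treat = p_t, p_control = p_c, rte = p_t_use / p_c_use,
       n_treat = length(treat_rates), n_control = length(control_rates),
       floored = floored)
}

#' Per-drug, per-stratum, per-outcome RTE table
#'
#' @param cohort A `pv_cohort` from [stratify()].
#' @param profiles Data frame from [outcome_profiles()].
#' @param drug_by_user Named character vector mapping treated user ids to
#'   generic drug names (controls need no entry).
#' @return Data frame with one row per (drug, retained stratum, outcome):
#'   `p_treat`, `p_control`, `rte`, arm sizes and the floor flag. Strata where
#'   a drug has no treated users are omitted.
#' @export
rte_table <- function(cohort, profiles, drug_by_user) {
  stopifnot(inherits(cohort, "pv_cohort"))
  asg <- cohort$assignment[cohort$assignment$retained, , drop = FALSE]
  asg <- asg[asg$user_id %in% profiles$user_id, , drop = FALSE]
  prof <- profiles[match(asg$user_id, profiles$user_id), , drop = FALSE]
  valid <- prof$n_post > 0
  asg <- asg[valid, , drop = FALSE]; prof <- prof[valid, , drop = FALSE]
  drugs <- sort(unique(stats::na.omit(drug_by_user[asg$user_id[asg$arm == "treatment"]])))
  pv_assert(length(drugs) > 0L, "no treated users with a drug label")
  rows <- list()
  for (s in sort(unique(asg$stratum))) {
    in_s <- asg$stratum == s
    ctrl <- in_s & asg$arm == "control"
    if (!any(ctrl)) next
    for (d in drugs) {
      trt <- in_s & asg$arm == "treatment" &
        drug_by_user[asg$user_id] %in% d
      if (!any(trt)) next
      for (o in OUTCOME_NAMES) {
        r <- stratum_rte(prof[[paste0("post_", o)]][trt],
                         prof[[paste0("post_", o)]][ctrl],
                         prof$n_post[trt], prof$n_post[ctrl])
        rows[[length(rows) + 1L]] <- data.frame(
          drug = d, stratum = s, outcome = o, p_treat = r$p_treat,
          p_control = r$p_control, rte = r$rte, n_treat = r$n_treat,
          n_control = r$n_control, floored = r$floored,
          stringsAsFactors = FALSE)
      }
    }
  }
  pv_assert(length(rows) > 0L, "no stratum had both arms populated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank strata by composite RTE and select most/least-improved cohorts
#'
#' The composite ranking key of a stratum is the unweighted mean over the
#' five outcomes of log(RTE). Since the outcomes are symptom expressions, a
#' LOWER symptomatic RTE means MORE improvement relative to matched controls;
#' by default strata are therefore sorted by ascending composite (most
#' improved first). `invert = TRUE` flips the convention for data sets where
#' the outcome measure is already improvement-oriented. Ties are broken by
#' ascending stratum index.
#'
#' @param rte_tbl Data frame from [rte_table()] (one drug, or filter by
#'   `drug`).
#' @param cohort The `pv_cohort` used to build the table.
#' @param k Number of strata per tail (default 10). If fewer than `2k`
#'   ranked strata exist, `k` shrinks with a warning.
#' @param drug Optional drug filter when the table covers several drugs.
#' @param invert Flip the improvement direction convention.
#' @param shrink Empirical-Bayes shrinkage strength (pseudo effective users)
#'   pulling thin strata toward the precision-weighted trend of the composite
#'   on the score midpoint; 0 disables stabilization (default 5).
#' @return List of class `pv_cohort_pair`: `most_improved` and
#'   `least_improved` treated user id vectors, the per-stratum `ranking`
#'   table, `k`, `drug` and the ranking-key description.
#' @export
rank_strata_and_select <- function(rte_tbl, cohort, k = 10L, drug = NULL,
                                   invert = FALSE, shrink = 5) {
  stopifnot(inherits(cohort, "pv_cohort"))
  if (!is.null(drug)) rte_tbl <- rte_tbl[rte_tbl$drug == drug, , drop = FALSE]
  pv_assert(nrow(rte_tbl) > 0L, "no RTE rows to rank (no retained strata?)")
  drug <- unique(rte_tbl$drug)
  pv_assert(length(drug) == 1L,
            "rte table covers several drugs; pass `drug` to select one")
  key <- tapply(log(rte_tbl$rte), rte_tbl$stratum, mean)
  # Empirical-Bayes stabilization: a stratum's mean log-RTE has sampling
  # variance proportional to 1/n_t + 1/n_c, so thin strata (one-user arms at
  # the score tails) would otherwise claim the extreme ranks by noise alone.
  # Each stratum is shrunk toward a precision-weighted linear trend of the
  # composite on the stratum's score midpoint, with residual weight
  # n_eff / (n_eff + shrink); shrink = 0 ranks the raw composites.
  n_t <- tapply(rte_tbl$n_treat, rte_tbl$stratum, max)
  n_c <- tapply(rte_tbl$n_control, rte_tbl$stratum, max)
  n_eff <- as.numeric(1 / (1 / n_t + 1 / n_c))
  strata_ids <- as.integer(names(key))
  mid <- (strata_ids + 0.5) / cohort$n_strata
  raw <- as.numeric(key)
  if (shrink > 0 && length(raw) > 2L && stats::sd(mid) > 0) {
    trend <- stats::lm.wfit(cbind(1, mid), raw, w = n_eff)
    fitted <- drop(cbind(1, mid) %*% trend$coefficients)
  } else {
    fitted <- rep(stats::weighted.mean(raw, n_eff), length(raw))
  }
  lam <- n_eff / (n_eff + shrink)
  stabilized <- fitted + lam * (raw - fitted)
  ranking <- data.frame(stratum = strata_ids,
                        mean_log_rte = raw,
                        n_eff = as.numeric(n_eff),
                        composite_log_rte = as.numeric(stabilized),
                        stringsAsFactors = FALSE)
  ord <- order(if (invert) -ranking$composite_log_rte else
               ranking$composite_log_rte, ranking$stratum)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  n_s <- nrow(ranking)
  pv_assert(n_s >= 2L, "need at least 2 ranked strata to form cohorts")
  k <- as.integer(k)
  if (n_s < 2L * k) {
    k <- n_s %/% 2L
    warning(sprintf("only %d ranked strata; shrinking k to %d", n_s, k))
  }
  top <- ranking$stratum[seq_len(k)]
  bottom <- ranking$stratum[seq(n_s - k + 1L, n_s)]
  asg <- cohort$assignment
  treated_in <- function(strata) sort(asg$user_id[asg$retained &
                                                  asg$arm == "treatment" &
                                                  asg$stratum %in% strata])
  most <- treated_in(top)
  least <- treated_in(bottom)
  structure(list(drug = drug, most_improved = most, least_improved = least,
                 k = k, ranking = ranking,
                 ranking_key = paste("mean over outcomes of log RTE;",
                                     if (invert) "descending = improved"
                                     else "ascending = improved")),
            class = "pv_cohort_pair")
}

#' @export
print.pv_cohort_pair <- function(x, ...) {
  cat(sprintf("<pv_cohort_pair> drug %s: %d most-improved, %d least-improved users (k = %d strata/tail)\n",
              x$drug, length(x$most_improved), length(x$least_improved), x$k))
  invisible(x)
}
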