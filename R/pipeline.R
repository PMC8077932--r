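#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_pipeline()] with the defaults used
#' throughout the package's analyses.
#'
#' @param seed Integer seed for the pipeline's random choices (intake
#'   training-set templates, control pseudo-disclosure sampling).
#' @param n_strata Equal-width propensity strata (default 100).
#' @param k Strata per tail for cohort selection (default 10).
#' @param top_v Top-unigram covariate cap (default 2000).
#' @param l2_penalty Propensity-model L2 penalty (default 1).
#' @param min_per_arm Stratum retention threshold per arm (default 1).
#' @param invert_rte Flip the improvement direction convention.
#' @param rte_shrink Stabilization strength for stratum ranking, see
#'   [rank_strata_and_select()].
#' @param sage_k Keywords reported per cohort (default 20).
#' @param sage_ngrams N-gram orders for keyword extraction (default 1-2).
#' @param sage_min_count SAGE vocabulary minimum pooled count (default 5).
#' @param prevalence_k Rows per side in the prevalence comparison.
#' @param prevalence_ngrams N-gram orders for co-occurrence prevalence.
#' @param intake_threshold Intake-classifier decision threshold.
#' @param intake_training_n Template training-set size.
#' @param min_pre_posts,min_post_posts Minimum window sizes for a user to
#'   enter the analysis.
#' @param verbose Echo stage log lines.
#' @return List of class `pv_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_strata = 100L, k = 10L,
                            top_v = 2000L, l2_penalty = 1, min_per_arm = 1L,
                            invert_rte = FALSE, rte_shrink = 5, sage_k = 20L,
                            sage_ngrams = c(1L, 2L), sage_min_count = 5,
                            prevalence_k = 15L, prevalence_ngrams = 1:3,
                            intake_threshold = 0.5, intake_training_n = 400L,
                            min_pre_posts = 1L, min_post_posts = 1L,
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pv_pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "pv_pipeline_error")) stop(e)
    pv_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)),
            "pv_pipeline_error", data = list(stage = stage, parent = e))
  })
}

# locate posts mentioning any lexicon term; returns post row indices plus the
# generic of the longest matching term per post
drug_mention_posts <- function(texts, lexicon) {
  terms <- lexicon_terms(lexicon)
  padded <- pad_tokens(tokenize_all(texts))
  # longest terms first so the recorded generic follows longest-match-wins
  terms <- terms[order(-nchar(terms$term)), , drop = FALSE]
  generic <- rep(NA_character_, length(texts))
  for (i in seq_len(nrow(terms))) {
    needle <- paste0(" ", paste(tokenize(terms$term[i]), collapse = " "), " ")
    hit <- is.na(generic) & grepl(needle, padded, fixed = TRUE)
    generic[hit] <- terms$generic[i]
  }
  data.frame(row = which(!is.na(generic)),
             generic = generic[!is.na(generic)], stringsAsFactors = FALSE)
}

#' Run the full pharmacovigilance analysis pipeline
#'
#' Executes lexicon -> intake -> features -> propensity -> effects -> SAGE ->
#' prevalence on a corpus: detects treated users from intake-classified drug
#' mentions, anchors control users at sampled pseudo-disclosure times, builds
#' pretreatment covariates, estimates and stratifies propensity scores,
#' computes per-drug per-stratum relative treatment effects over the five
#' symptomatic outcomes, selects most/least-improved cohorts, and extracts
#' contrastive keywords and side-effect co-occurrence prevalence from the
#' cohorts' post-treatment text. Deterministic given `config$seed`. Any stage
#' error aborts with the stage name.
#'
#' @param corpus A `pv_corpus` or the path of a JSON-lines corpus readable by
#'   [read_corpus()].
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every intermediate table and
#'   the run log are written there as TSV/text.
#' @return A list of class `pv_result` bundling all intermediates: treated
#'   user table, covariates, propensity model and scores, stratified cohort,
#'   balance diagnostics, RTE table, per-drug cohort pairs, keywords and
#'   prevalence tables, and the run log.
#' @export
run_pipeline <- function(corpus, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pv_pipeline_config"))
  logger <- pv_logger(config$verbose)
  set.seed(config$seed)
  if (is.character(corpus)) corpus <- with_stage("read", read_corpus(corpus))
  stopifnot(inherits(corpus, "pv_corpus"))
  posts <- corpus$posts

  lexicon <- with_stage("lexicon", load_lexicon())
  logger$log("lexicon: %d generics", nrow(lexicon))

  intake <- with_stage("intake", {
    clf <- train_intake_classifier(
      make_intake_training_set(lexicon, config$intake_training_n),
      threshold = config$intake_threshold)
    mentions <- drug_mention_posts(posts$text, lexicon)
    if (nrow(mentions) == 0L)
      pv_stop("no drug mentions found; corpus has no treated users",
              "pv_no_treated_error")
    cls <- classify_intake(posts$text[mentions$row], clf)
    hits <- mentions[cls$intake, , drop = FALSE]
    if (nrow(hits) == 0L)
      pv_stop("no posts classified as personal intake; corpus has no treated users",
              "pv_no_treated_error")
    hp <- posts[hits$row, c("post_id", "user_id", "timestamp")]
    hp$generic <- hits$generic
    hp <- hp[order(hp$user_id, hp$timestamp, hp$post_id), , drop = FALSE]
    first <- hp[!duplicated(hp$user_id), , drop = FALSE]
    list(classifier = clf,
         treated = data.frame(user_id = first$user_id, drug = first$generic,
                              disclosure_time = first$timestamp,
                              stringsAsFactors = FALSE))
  })
  treated <- intake$treated
  logger$log("intake: %d treated users detected", nrow(treated))

  feats <- with_stage("features", {
    all_users <- unique(posts$user_id)
    controls <- setdiff(all_users, treated$user_id)
    anchors <- c(stats::setNames(treated$disclosure_time, treated$user_id),
                 sample_pseudo_disclosures(controls, treated$disclosure_time))
    anchors <- anchors[all_users]
    markers <- load_outcome_markers()
    profiles <- outcome_profiles(corpus, anchors, markers)
    eligible <- profiles$user_id[profiles$n_pre >= config$min_pre_posts &
                                 profiles$n_post >= config$min_post_posts]
    pv_assert(length(eligible) > 0L, "no users with non-empty pre and post windows")
    exclude <- unique(c(unlist(tokenize_all(lexicon_terms(lexicon)$term)),
                        "i", "took"))
    covs <- covariate_table(corpus, anchors[eligible], top_unigrams = NULL,
                            markers = markers, v = config$top_v,
                            exclude_tokens = exclude)
    list(anchors = anchors, profiles = profiles, covariates = covs,
         eligible = covs$user_id, markers = markers)
  })
  logger$log("features: %d eligible users, %d covariates",
             length(feats$eligible), ncol(feats$covariates) - 1L)

  prop <- with_stage("propensity", {
    trt <- stats::setNames(feats$eligible %in% treated$user_id, feats$eligible)
    model <- fit_propensity(feats$covariates, trt,
                            l2_penalty = config$l2_penalty)
    scores <- predict_propensity(model, feats$covariates)
    cohort <- stratify(scores, trt, n_strata = config$n_strata,
                       min_per_arm = config$min_per_arm)
    balance <- balance_diagnostics(cohort, feats$covariates)
    list(model = model, scores = scores, cohort = cohort, balance = balance)
  })
  logger$log("propensity: %d/%d strata retained",
             sum(prop$cohort$strata$retained), config$n_strata)

  eff <- with_stage("effects", {
    drug_by_user <- stats::setNames(treated$drug, treated$user_id)
    rte <- rte_table(prop$cohort, feats$profiles, drug_by_user)
    pairs <- lapply(sort(unique(rte$drug)), function(d)
      rank_strata_and_select(rte, prop$cohort, k = config$k, drug = d,
                             invert = config$invert_rte,
                             shrink = config$rte_shrink))
    names(pairs) <- sort(unique(rte$drug))
    list(rte = rte, cohort_pairs = pairs)
  })
  logger$log("effects: RTE over %d strata, %d drug(s)",
             length(unique(eff$rte$stratum)), length(eff$cohort_pairs))

  post_texts <- function(uids) {
    sel <- posts$user_id %in% uids &
      posts$timestamp > feats$anchors[posts$user_id]
    posts$text[sel]
  }
  sage <- with_stage("sage", {
    lapply(eff$cohort_pairs, function(cp)
      contrastive_keywords(post_texts(cp$most_improved),
                           post_texts(cp$least_improved),
                           ngram_orders = config$sage_ngrams,
                           k = config$sage_k,
                           min_count = config$sage_min_count))
  })
  logger$log("sage: keywords extracted for %d drug(s)", length(sage))

  prev <- with_stage("prevalence", {
    seeds <- unlist(load_side_effect_seeds(), use.names = FALSE)
    lapply(eff$cohort_pairs, function(cp) {
      ti <- cooccurrence_prevalence(post_texts(cp$most_improved), seeds,
                                    ngram_orders = config$prevalence_ngrams)
      tw <- cooccurrence_prevalence(post_texts(cp$least_improved), seeds,
                                    ngram_orders = config$prevalence_ngrams)
      list(improved = ti, worsened = tw,
           comparison = compare_prevalence(ti, tw, k = config$prevalence_k))
    })
  })
  logger$log("prevalence: co-occurrence tables built")

  result <- structure(list(lexicon = lexicon, intake = intake,
                           anchors = feats$anchors, profiles = feats$profiles,
                           covariates = feats$covariates,
                           propensity = prop$model, scores = prop$scores,
                           cohort = prop$cohort, balance = prop$balance,
                           rte = eff$rte, cohort_pairs = eff$cohort_pairs,
                           keywords = sage, prevalence = prev,
                           log = logger$lines(), config = config),
                      class = "pv_result")
  if (!is.null(outdir)) write_result(result, outdir)
  result
}

#' Write a pipeline result bundle to a directory
#'
#' @param result A `pv_result`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  pv_write_tsv(result$intake$treated, p("treated_users.tsv"))
  pv_write_tsv(result$cohort$assignment, p("cohort_assignment.tsv"))
  pv_write_tsv(result$balance, p("balance_diagnostics.tsv"))
  pv_write_tsv(result$rte, p("rte_table.tsv"))
  pairs <- do.call(rbind, lapply(result$cohort_pairs, function(cp)
    data.frame(drug = cp$drug,
               cohort = rep(c("most_improved", "least_improved"),
                            c(length(cp$most_improved),
                              length(cp$least_improved))),
               user_id = c(cp$most_improved, cp$least_improved),
               stringsAsFactors = FALSE)))
  pv_write_tsv(pairs, p("cohorts.tsv"))
  kw <- do.call(rbind, lapply(names(result$keywords), function(d) {
    k <- result$keywords[[d]]
    rbind(cbind(drug = d, cohort = "most_improved", k$a[, c("term", "eta", "rank")]),
          cbind(drug = d, cohort = "least_improved", k$b[, c("term", "eta", "rank")]))
  }))
  pv_write_tsv(kw, p("sage_keywords.tsv"))
  pr <- do.call(rbind, lapply(names(result$prevalence), function(d)
    cbind(drug = d, result$prevalence[[d]]$comparison)))
  pv_write_tsv(pr, p("prevalence_comparison.tsv"))
  writeLines(result$log, p("run_log.txt"))
  invisible(outdir)
}

#' @export
print.pv_result <- function(x, ...) {
  cat(sprintf("<pv_result> %d treated users, %d strata retained, drugs: %s\n",
              nrow(x$intake$treated), sum(x$cohort$strata$retained),
              paste(names(x$cohort_pairs), collapse = ", ")))
  invisible(x)
}
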