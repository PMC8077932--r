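#' Load a psycholinguistic category lexicon
#'
#' A pluggable category -> word-list table. The packaged fixture is a small
#' open five-category lexicon (positive/negative affect, social, cognitive,
#' body); proprietary psycholinguistic dictionaries can be supplied in the
#' same TSV format (columns `category`, `words` pipe-separated).
#'
#' @param path TSV path, or `NULL` for the packaged fixture.
#' @return Named list of character vectors.
#' @export
load_psycholing <- function(path = NULL) {
  path <- path %||% pv_extdata("psycholing_categories.tsv")
  df <- pv_read_tsv(path, colClasses = "character")
  pv_assert(all(c("category", "words") %in% names(df)),
            "psycholinguistic lexicon needs columns category, words")
  out <- lapply(df$words, function(w) tolower(strsplit(w, "|", fixed = TRUE)[[1L]]))
  names(out) <- df$category
  out
}

#' Pseudo-disclosure times for control users
#'
#' Control users have no intake disclosure, but their covariates and outcome
#' windows must be anchored the same way as treated users'. Times are sampled
#' (from the current RNG stream; seed upstream) from the empirical
#' distribution of the treated users' disclosure times, which balances
#' pre/post window lengths across arms.
#'
#' @param user_ids Character vector of control user ids.
#' @param treated_disclosures Numeric vector of treated disclosure times.
#' @return Named numeric vector of pseudo-disclosure times.
#' @export
sample_pseudo_disclosures <- function(user_ids, treated_disclosures) {
  pv_assert(length(treated_disclosures) > 0L,
            "need at least one treated disclosure time to sample from")
  stats::setNames(sample(rep(treated_disclosures, 2L), length(user_ids),
                         replace = TRUE), user_ids)
}

#' Top-V pretreatment unigram vocabulary
#'
#' Ranks unigrams by corpus-wide frequency over pretreatment text and keeps
#' the top `V`, excluding a supplied list (drug names and intake-template
#' tokens, to avoid treatment-label leakage into the propensity model).
#'
#' @param token_lists List of token vectors (pretreatment posts only).
#' @param v Vocabulary size cap (default 2000).
#' @param exclude Tokens to exclude.
#' @return Character vector of at most `v` unigrams, by descending frequency.
#' @export
top_unigram_vocab <- function(token_lists, v = 2000L, exclude = character(0)) {
  toks <- unlist(token_lists, use.names = FALSE)
  toks <- toks[!(toks %in% exclude)]
  if (length(toks) == 0L) return(character(0))
  tab <- sort(table(toks), decreasing = TRUE)
  head(names(tab), v)
}

# internal worker shared by covariate_table() and build_covariates():
# per-user aggregation of pretreatment tokens into the covariate blocks.
covariates_from_blocks <- function(pre_tokens_by_user, users_profile,
                                   n_pre_posts, psycholing, top_unigrams,
                                   baseline_rates) {
  uids <- names(pre_tokens_by_user)
  totals <- vapply(pre_tokens_by_user, length, integer(1))
  # psycholinguistic relative frequencies
  psy <- vapply(psycholing, function(words) {
    vapply(seq_along(uids), function(i) {
      if (totals[i] == 0L) return(0)
      sum(pre_tokens_by_user[[i]] %in% words) / totals[i]
    }, numeric(1))
  }, numeric(length(uids)))
  if (length(uids) == 1L) psy <- matrix(psy, nrow = 1L,
                                        dimnames = list(NULL, names(psycholing)))
  colnames(psy) <- paste0("pl_", names(psycholing))
  # top-V unigram relative frequencies
  if (length(top_unigrams) > 0L) {
    ug <- matrix(0, nrow = length(uids), ncol = length(top_unigrams),
                 dimnames = list(NULL, paste0("ug_", top_unigrams)))
    for (i in seq_along(uids)) {
      if (totals[i] == 0L) next
      t_i <- pre_tokens_by_user[[i]]
      cnt <- table(factor(t_i[t_i %in% top_unigrams], levels = top_unigrams))
      ug[i, ] <- as.numeric(cnt) / totals[i]
    }
  } else {
    ug <- matrix(numeric(0), nrow = length(uids), ncol = 0L)
  }
  prof <- users_profile[match(uids, users_profile$user_id), , drop = FALSE]
  out <- data.frame(user_id = uids,
                    log_followers = log1p(prof$n_followers),
                    log_posts = log1p(n_pre_posts[uids]),
                    tenure_days = prof$tenure_days,
                    stringsAsFactors = FALSE)
  out <- cbind(out, psy, ug, baseline_rates[match(uids, rownames(baseline_rates)), ,
                                            drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Pretreatment covariate table for a corpus
#'
#' Builds one covariate row per user from posts strictly before the user's
#' (pseudo-)disclosure time: structural features (log followers, log
#' pretreatment post count, tenure), psycholinguistic category frequencies,
#' top-V unigram frequencies, and baseline symptomatic outcome rates for the
#' five outcomes. Users with zero pretreatment posts are flagged and dropped
#' from the returned table (ids in `attr(, "excluded")`).
#'
#' @param corpus A `pv_corpus`.
#' @param disclosure_times Named numeric vector (user -> anchor time) covering
#'   every user to featurize.
#' @param psycholing Psycholinguistic lexicon, see [load_psycholing()].
#' @param top_unigrams Unigram vocabulary, see [top_unigram_vocab()]; `NULL`
#'   computes it from this corpus's pretreatment text with `v`.
#' @param markers Outcome marker config, see [load_outcome_markers()].
#' @param v Top-unigram cap used when `top_unigrams` is `NULL`.
#' @param exclude_tokens Tokens excluded from the unigram vocabulary.
#' @return Data frame of covariates, one row per retained user; attribute
#'   `excluded` lists users with no pretreatment posts.
#' @export
covariate_table <- function(corpus, disclosure_times, psycholing = NULL,
                            top_unigrams = NULL, markers = NULL, v = 2000L,
                            exclude_tokens = character(0)) {
  stopifnot(inherits(corpus, "pv_corpus"))
  psycholing <- psycholing %||% load_psycholing()
  markers <- markers %||% load_outcome_markers()
  uids <- names(disclosure_times)
  posts <- corpus$posts[corpus$posts$user_id %in% uids, , drop = FALSE]
  anchor <- disclosure_times[posts$user_id]
  pre <- posts[posts$timestamp < anchor, , drop = FALSE]

  pre_tok <- tokenize_all(pre$text)
  if (is.null(top_unigrams))
    top_unigrams <- top_unigram_vocab(pre_tok, v = v, exclude = exclude_tokens)

  user_f <- factor(pre$user_id, levels = uids)
  tokens_by_user <- split(pre_tok, user_f)
  tokens_by_user <- lapply(tokens_by_user, function(l) unlist(l, use.names = FALSE))
  n_pre <- vapply(split(seq_len(nrow(pre)), user_f), length, integer(1))

  # baseline outcome rates from an independent per-post scoring pass
  flags <- score_posts(pre$text, markers)
  base <- matrix(0, nrow = length(uids), ncol = length(markers),
                 dimnames = list(uids, paste0("base_", names(markers))))
  for (o in seq_along(markers)) {
    pos <- tapply(flags[, o], user_f, sum)
    pos[is.na(pos)] <- 0
    base[, o] <- ifelse(n_pre > 0, pos / pmax(n_pre, 1L), 0)
  }

  excluded <- uids[n_pre == 0L]
  keep <- uids[n_pre > 0L]
  out <- covariates_from_blocks(tokens_by_user[keep], corpus$users,
                                n_pre, psycholing, top_unigrams,
                                base)
  out <- out[out$user_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "top_unigrams") <- top_unigrams
  out
}

#' Covariate vector for a single user timeline
#'
#' Single-user convenience wrapper around [covariate_table()]; returns the
#' blocks of the covariate vector as named lists. Posts at or after
#' `disclosure_time` never influence the result.
#'
#' @inheritParams covariate_table
#' @param user_id User to featurize.
#' @param disclosure_time Anchor time (real or pseudo disclosure).
#' @return List with elements `structural`, `psycholing`, `unigrams`,
#'   `baseline_outcomes`, `n_pre_posts`, `excluded`.
#' @export
build_covariates <- function(corpus, user_id, disclosure_time,
                             psycholing = NULL, top_unigrams = NULL,
                             markers = NULL) {
  tab <- covariate_table(corpus, stats::setNames(disclosure_time, user_id),
                         psycholing = psycholing, top_unigrams = top_unigrams,
                         markers = markers)
  if (nrow(tab) == 0L)
    return(list(structural = NULL, psycholing = NULL, unigrams = NULL,
                baseline_outcomes = NULL, n_pre_posts = 0L, excluded = TRUE))
  row <- tab[1L, , drop = FALSE]
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix), names(row), value = TRUE)
    stats::setNames(as.numeric(row[1L, cols]), sub(paste0("^", prefix), "", cols))
  }
  list(structural = c(log_followers = row$log_followers,
                      log_posts = row$log_posts,
                      tenure_days = row$tenure_days),
       psycholing = grab("pl_"),
       unigrams = grab("ug_"),
       baseline_outcomes = grab("base_"),
       n_pre_posts = as.integer(round(expm1(row$log_posts))),
       excluded = FALSE)
}
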