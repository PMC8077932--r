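#' Load side-effect seed-term lists
#'
#' YAML mapping side-effect categories (the packaged file covers sleep,
#' weight, eating, pain and sexual issues) to seed terms.
#'
#' @param path YAML path, or `NULL` for the packaged lists.
#' @return Named list of character vectors.
#' @export
load_side_effect_seeds <- function(path = NULL) {
  path <- path %||% pv_extdata("side_effect_seeds.yaml")
  raw <- yaml::read_yaml(path)
  pv_assert(length(raw) > 0L, "seed list file is empty")
  lapply(raw, function(x) tolower(as.character(x)))
}

# token index spans (1-based, inclusive) of every seed occurrence
seed_spans <- function(tokens, seed_tokens_list) {
  spans <- list()
  for (st in seed_tokens_list) {
    L <- length(st)
    if (L == 0L || length(tokens) < L) next
    starts <- seq_len(length(tokens) - L + 1L)
    for (s in starts) {
      if (all(tokens[s:(s + L - 1L)] == st))
        spans[[length(spans) + 1L]] <- c(s, s + L - 1L)
    }
  }
  spans
}

#' Normalized co-occurrence prevalence of n-grams with seed terms
#'
#' For every post containing at least one seed term, collects the post's
#' n-grams excluding any n-gram overlapping a seed occurrence itself, and
#' reports for each n-gram the fraction of ALL posts in the corpus that are
#' seed-co-occurring posts containing it (the normalized prevalence of
#' side-effect co-occurrence bar charts).
#'
#' @param texts Character vector of posts (one corpus).
#' @param seed_terms Character vector of seed terms (multiword allowed).
#' @param ngram_orders N-gram orders to collect (default `1:3`).
#' @return Data frame with columns `term`, `n_posts` (co-occurring posts
#'   containing the term) and `prevalence`, sorted by descending prevalence
#'   then term. Empty when no post contains a seed.
#' @export
cooccurrence_prevalence <- function(texts, seed_terms, ngram_orders = 1:3) {
  pv_assert(length(seed_terms) > 0L, "seed_terms must be non-empty")
  total <- length(texts)
  empty <- data.frame(term = character(0), n_posts = integer(0),
                      prevalence = numeric(0), stringsAsFactors = FALSE)
  if (total == 0L) return(empty)
  toks <- tokenize_all(texts)
  seeds_tok <- lapply(seed_terms, tokenize)
  per_post <- lapply(toks, function(t) {
    spans <- seed_spans(t, seeds_tok)
    if (length(spans) == 0L) return(NULL)
    grams <- character(0)
    for (n in ngram_orders) {
      if (length(t) < n) next
      starts <- seq_len(length(t) - n + 1L)
      ok <- vapply(starts, function(s) {
        e <- s + n - 1L
        !any(vapply(spans, function(sp) s <= sp[2L] && e >= sp[1L], logical(1)))
      }, logical(1))
      if (any(ok)) grams <- c(grams, ngrams(t, n)[ok])
    }
    unique(grams)
  })
  grams <- unlist(per_post, use.names = FALSE)
  if (length(grams) == 0L) return(empty)
  tab <- table(grams)
  out <- data.frame(term = names(tab), n_posts = as.integer(tab),
                    prevalence = as.numeric(tab) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Side-by-side prevalence comparison across two cohorts
#'
#' Takes the union of the top-`k` terms of either table (by that table's
#' prevalence), reports both normalized prevalences (0 when a term is absent
#' from a cohort) and sorts by the larger of the two.
#'
#' @param table_improved,table_worsened Outputs of
#'   [cooccurrence_prevalence()] built from the same seed list.
#' @param k Top terms per side (default 15).
#' @return Data frame with columns `term`, `prevalence_improved`,
#'   `prevalence_worsened`.
#' @export
compare_prevalence <- function(table_improved, table_worsened, k = 15L) {
  pick <- function(tab) utils::head(tab$term, k)
  terms <- union(pick(table_improved), pick(table_worsened))
  get <- function(tab, term) {
    i <- match(term, tab$term)
    ifelse(is.na(i), 0, tab$prevalence[i])
  }
  out <- data.frame(term = terms,
                    prevalence_improved = get(table_improved, terms),
                    prevalence_worsened = get(table_worsened, terms),
                    stringsAsFactors = FALSE)
  out <- out[order(-pmax(out$prevalence_improved, out$prevalence_worsened),
                   out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
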