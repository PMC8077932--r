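# Personal medication-intake classification: separating posts that report
# actually taking a drug from posts that merely mention one. A regularized
# linear (logistic-loss) classifier over token and first-person-pattern
# features; the decision threshold is exposed. The feature design follows
# the intuition that self-reports are marked by first-person constructions
# ("i took ...", "my ... dose") rather than by the drug name itself.

FIRST_PERSON <- c("i", "im", "ive", "me", "my")

intake_features <- function(texts, vocab = NULL) {
  toks <- tokenize_all(texts)
  feats <- lapply(toks, function(t) {
    bi <- ngrams(t, 2L)
    bi <- bi[sub(" .*", "", bi) %in% FIRST_PERSON]
    fp <- if (length(bi) > 0L) paste0("fp:", bi) else character(0)
    unique(c(t, fp))
  })
  if (is.null(vocab)) {
    tab <- table(unlist(feats, use.names = FALSE))
    vocab <- sort(names(tab)[tab >= 2L])
  }
  X <- matrix(0, nrow = length(texts), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(feats)) {
    hit <- intersect(feats[[i]], vocab)
    if (length(hit) > 0L) X[i, hit] <- 1
  }
  X
}

#' Train the personal medication-intake classifier
#'
#' Regularized logistic-loss linear model over binary token-presence and
#' first-person bigram-pattern features. Training is deterministic: the
#' optimizer is penalized IRLS and the feature vocabulary is a sorted set.
#'
#' @param labeled_posts Data frame with columns `text` and `label` (logical
#'   or 0/1; TRUE = personal intake). At least 20 posts per class.
#' @param lambda L2 penalty (default 1).
#' @param threshold Decision threshold on the intake probability
#'   (default 0.5).
#' @return A list of class `pv_intake` with the feature weight map, bias and
#'   threshold.
#' @export
train_intake_classifier <- function(labeled_posts, lambda = 1,
                                    threshold = 0.5) {
  pv_assert(all(c("text", "label") %in% names(labeled_posts)),
            "labeled_posts needs columns text, label")
  y <- as.numeric(as.logical(labeled_posts$label))
  if (length(unique(y)) < 2L)
    pv_stop("training set has a single class", "pv_degenerate_error")
  pv_assert(min(table(y)) >= 20L, "need at least 20 posts per class")
  X <- intake_features(labeled_posts$text)
  fit <- fit_logistic_irls(X, y, lambda = lambda, standardize = FALSE)
  structure(list(weights = fit$coefficients, bias = fit$intercept,
                 threshold = threshold, features = fit$feature_order),
            class = "pv_intake")
}

#' Classify posts as personal intake reports
#'
#' @param texts Character vector of posts.
#' @param classifier A `pv_intake` model.
#' @return Data frame with columns `score` (probability in `[0, 1]`) and
#'   `intake` (`score >= threshold`).
#' @export
classify_intake <- function(texts, classifier) {
  stopifnot(inherits(classifier, "pv_intake"))
  X <- intake_features(texts, vocab = classifier$features)
  score <- stats::plogis(classifier$bias +
                         drop(X %*% classifier$weights[classifier$features]))
  data.frame(score = score, intake = score >= classifier$threshold)
}

#' Serialize / restore an intake classifier as JSON
#'
#' @param classifier A `pv_intake`.
#' @param path JSON file path.
#' @return `path` (write) or a `pv_intake` (read).
#' @export
write_intake_classifier <- function(classifier, path) {
  jsonlite::write_json(list(weights = as.list(classifier$weights),
                            bias = classifier$bias,
                            threshold = classifier$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intake_classifier
#' @export
read_intake_classifier <- function(path) {
  raw <- jsonlite::fromJSON(path)
  w <- unlist(raw$weights)
  structure(list(weights = w, bias = raw$bias, threshold = raw$threshold,
                 features = names(w)),
            class = "pv_intake")
}

#' Template-generated training set for the intake classifier
#'
#' Builds a balanced labeled set of intake self-reports versus mere drug
#' mentions from phrase templates over the lexicon's terms, using the current
#' RNG stream. This stands in for the manually annotated training data of
#' production intake classifiers, with the same input/output contract.
#'
#' @param lexicon A `pv_lexicon`.
#' @param n Total number of posts (split evenly).
#' @return Data frame with columns `text`, `label`.
#' @export
make_intake_training_set <- function(lexicon, n = 400L) {
  terms <- lexicon_terms(lexicon)$term
  pv_assert(length(terms) > 0L, "lexicon has no terms")
  pos_tpl <- c("i took %s", "i took %s today", "i took my %s this morning",
               "just took my %s", "i started taking %s last week",
               "my doctor put me on %s and i took the first dose")
  neg_tpl <- c("%s is in the news again", "my friend takes %s",
               "they put her on %s", "read an article about %s side effects",
               "the pharmacy was out of %s", "is %s the same as the generic",
               "%s ads are everywhere", "she said %s helped her cousin")
  half <- max(20L, n %/% 2L)
  pos <- sprintf(sample(rep(pos_tpl, 2L), half, replace = TRUE),
                 sample(rep(terms, 2L), half, replace = TRUE))
  neg <- sprintf(sample(rep(neg_tpl, 2L), half, replace = TRUE),
                 sample(rep(terms, 2L), half, replace = TRUE))
  data.frame(text = c(pos, neg), label = rep(c(TRUE, FALSE), each = half),
             stringsAsFactors = FALSE)
}
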