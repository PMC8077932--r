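# Sparse additive generative (SAGE) contrastive model.
#
# A target corpus is modelled as a multinomial with log-probabilities
# m + eta (up to normalization), where m is the smoothed background
# log-frequency vector and eta a sparse deviation. eta carries a zero-mean
# Normal prior whose per-term variance tau is a latent variable under the
# parameter-free Jeffreys hyperprior p(tau) ~ 1/tau -- this is the
# "self-tuned" regularization: no penalty constant is hand-set, and the
# E-step E[1/tau | eta] = 1/eta^2 adaptively shrinks weak deviations to zero
# while leaving strong ones nearly unpenalized. The M-step is one Newton
# update with a Sherman-Morrison Hessian inverse (O(vocabulary) per round)
# and step-halving. eta^2 is floored at a small epsilon so the weights and
# the tracked penalized objective
#     loglik(eta) - 1/2 * sum(log(eta^2 + epsilon))
# stay finite; by a standard majorize-minimize argument this objective is
# non-decreasing across EM rounds. The first update (ridge weight 1, from
# eta = 0) is the initialization step, not an EM round.

#' Packaged function-word stopword list
#'
#' @return Character vector of stopword tokens used by default in
#'   [contrastive_keywords()].
#' @export
pv_stopwords <- function() {
  words <- readLines(pv_extdata("stopwords.txt"))
  words[nzchar(words)]
}

drop_stopword_ngrams <- function(counts, stopwords) {
  if (length(stopwords) == 0L || length(counts) == 0L) return(counts)
  keep <- vapply(strsplit(names(counts), " ", fixed = TRUE),
                 function(t) !any(t %in% stopwords), logical(1))
  counts[keep]
}

sage_loglik <- function(eta, m, counts) {
  sum(counts * eta) - sum(counts) * logsumexp(m + eta)
}

sage_penalized_objective <- function(eta, m, counts, epsilon) {
  sage_loglik(eta, m, counts) - 0.5 * sum(log(eta^2 + epsilon))
}

# M-step: damped Newton iterations on the quadratically-penalized surrogate
# S(eta) = counts'eta - C*lse(m+eta) - 1/2 sum(omega eta^2), run to
# (approximate) convergence so one badly scaled coordinate cannot stall the
# whole update. Each Newton direction uses the exact Hessian inverse via
# Sherman-Morrison (the Hessian is diagonal plus rank one), and step-halving
# guarantees the surrogate never decreases.
sage_newton_step <- function(eta, m, counts, omega, iteration,
                             inner_max = 25L, inner_tol = 1e-6) {
  C <- sum(counts)
  surrogate <- function(e) sum(counts * e) - C * logsumexp(m + e) -
    0.5 * sum(omega * e^2)
  s0 <- surrogate(eta)
  for (inner in seq_len(inner_max)) {
    p <- exp(m + eta - logsumexp(m + eta))
    g <- counts - C * p - omega * eta
    A <- C * p + omega                    # diag of (negated) Hessian
    u <- sqrt(C) * p                      # rank-one part: H = diag(A) - u u'
    Ainv_g <- g / A
    Ainv_u <- u / A
    denom <- 1 - sum(u * Ainv_u)
    delta <- Ainv_g + Ainv_u * (sum(u * Ainv_g) / denom)
    if (!all(is.finite(delta)))
      pv_stop(sprintf("non-finite SAGE update at iteration %d", iteration),
              "pv_numeric_error",
              data = list(iteration = iteration, eta = eta, omega = omega))
    step <- 1
    improved <- FALSE
    for (h in 1:40) {
      cand <- eta + step * delta
      s1 <- surrogate(cand)
      if (s1 > s0) { eta <- cand; s0 <- s1; improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved || max(abs(step * delta)) < inner_tol) break
  }
  eta
}

#' Fit a SAGE contrastive model
#'
#' Estimates sparse deviations `eta` of a target corpus's term distribution
#' from a background distribution, with self-tuned per-term regularization
#' (see the model notes in the source and the methods vignette). Terms with a
#' genuinely elevated rate in the target retain large positive `eta`; terms
#' whose deviation is statistical noise are shrunk to (numerically) zero.
#'
#' @param target_counts Named numeric vector of term counts for the target
#'   corpus.
#' @param background_counts Named numeric vector of background term counts.
#' @param max_iter Maximum EM rounds (default 50).
#' @param tolerance Convergence threshold on `max |delta eta|` (default 1e-4).
#' @param min_count Minimum pooled (target + background) count for a term to
#'   enter the vocabulary (default 5).
#' @param vocab_cap Maximum vocabulary size; highest pooled counts kept,
#'   ties lexicographic (default 5000).
#' @param epsilon Variance floor of the self-tuning step (default 1e-8).
#' @return A list of class `pv_sage_fit`: `vocabulary`, `m` (background
#'   log-probabilities; `exp(m)` sums to 1), `eta`, `tau` (= `eta^2 +
#'   epsilon`), `n_iterations`, `converged`, and the per-round penalized
#'   `objective` trace.
#' @export
fit_sage <- function(target_counts, background_counts, max_iter = 50L,
                     tolerance = 1e-4, min_count = 5, vocab_cap = 5000L,
                     epsilon = 1e-8) {
  pv_assert(length(target_counts) > 0L && sum(target_counts) > 0,
            "target corpus is empty")
  terms <- union(names(target_counts), names(background_counts))
  tc <- stats::setNames(rep(0, length(terms)), terms)
  tc[names(target_counts)] <- target_counts
  bc <- stats::setNames(rep(0, length(terms)), terms)
  bc[names(background_counts)] <- background_counts
  pooled <- tc + bc
  keep <- names(pooled)[pooled >= min_count]
  keep <- keep[order(-pooled[keep], keep)]
  if (length(keep) > vocab_cap) keep <- keep[seq_len(vocab_cap)]
  keep <- sort(keep)
  pv_assert(length(keep) > 0L,
            sprintf("no term reaches the minimum pooled count of %g", min_count))
  pv_assert(sum(tc[keep]) > 0,
            "target and background vocabularies are disjoint after thresholding")

  counts <- tc[keep]
  bg <- bc[keep] + 0.01
  m <- log(bg) - log(sum(bg))

  eta <- rep(0, length(keep))
  # initialization: one ridge(1) step away from eta = 0
  eta <- sage_newton_step(eta, m, counts, omega = rep(1, length(eta)),
                          iteration = 0L)
  objective <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    omega <- 1 / (eta^2 + epsilon)           # E-step: E[1/tau | eta]
    eta_new <- sage_newton_step(eta, m, counts, omega, iteration = it)
    objective <- c(objective, sage_penalized_objective(eta_new, m, counts,
                                                       epsilon))
    delta_max <- max(abs(eta_new - eta))
    eta <- eta_new
    n_iter <- it
    if (delta_max < tolerance) { converged <- TRUE; break }
  }
  structure(list(vocabulary = keep,
                 m = stats::setNames(m, keep),
                 eta = stats::setNames(eta, keep),
                 tau = stats::setNames(eta^2 + epsilon, keep),
                 n_iterations = n_iter, converged = converged,
                 objective = objective, epsilon = epsilon,
                 target_total = sum(counts)),
            class = "pv_sage_fit")
}

#' @export
print.pv_sage_fit <- function(x, ...) {
  cat(sprintf("<pv_sage_fit> %d terms, %d EM rounds (%sconverged), %d terms with |eta| > 0.1\n",
              length(x$vocabulary), x$n_iterations,
              if (x$converged) "" else "NOT ", sum(abs(x$eta) > 0.1)))
  invisible(x)
}

#' Top distinctive terms of a SAGE fit
#'
#' @param fit A `pv_sage_fit`.
#' @param k Number of terms (largest positive `eta` first; ties broken
#'   lexicographically). `k` larger than the vocabulary is truncated with a
#'   warning.
#' @return Data frame with columns `term`, `eta`, `rank`.
#' @export
top_terms <- function(fit, k) {
  stopifnot(inherits(fit, "pv_sage_fit"))
  k <- as.integer(k)
  if (k > length(fit$vocabulary)) {
    warning(sprintf("k = %d exceeds vocabulary size %d; truncating", k,
                    length(fit$vocabulary)))
    k <- length(fit$vocabulary)
  }
  if (k <= 0L)
    return(data.frame(term = character(0), eta = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  ord <- order(-fit$eta, fit$vocabulary)[seq_len(k)]
  data.frame(term = fit$vocabulary[ord], eta = unname(fit$eta[ord]),
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Contrastive keywords between two corpora
#'
#' Fits SAGE twice -- each corpus as target against the pooled background of
#' both -- and reports each side's top distinctive terms. The background is
#' the equal-weight mixture of the two corpora's term distributions (scaled
#' to the pooled token count): raw summed counts would let the larger corpus
#' dominate the background and mask its own enrichments whenever cohort
#' sizes are unbalanced, as they routinely are for top- vs bottom-strata
#' cohorts. This is the keyword-extraction step applied to the
#' post-treatment text of the most- vs least-improved cohorts.
#'
#' @param corpus_a,corpus_b Character vectors of documents.
#' @param ngram_orders N-gram orders entering the shared multinomial
#'   (default `c(1, 2)`).
#' @param k Keywords per side (default 20).
#' @param min_count,vocab_cap,max_iter,tolerance Passed to [fit_sage()].
#' @param stopwords Tokens whose n-grams are excluded from the keyword
#'   vocabulary (any n-gram containing one is dropped); defaults to the
#'   packaged function-word list, `character(0)` disables filtering.
#' @return List of class `pv_keywords` with elements `a` and `b`, each a
#'   `top_terms()` data frame plus a `target` label attribute, and the two
#'   fits under `fit_a`, `fit_b`.
#' @export
contrastive_keywords <- function(corpus_a, corpus_b, ngram_orders = c(1L, 2L),
                                 k = 20L, min_count = 5, vocab_cap = 5000L,
                                 max_iter = 50L, tolerance = 1e-4,
                                 stopwords = pv_stopwords()) {
  pv_assert(length(corpus_a) > 0L && length(corpus_b) > 0L,
            "both corpora must be non-empty")
  ca <- drop_stopword_ngrams(ngram_counts(corpus_a, orders = ngram_orders),
                             stopwords)
  cb <- drop_stopword_ngrams(ngram_counts(corpus_b, orders = ngram_orders),
                             stopwords)
  pv_assert(sum(ca) > 0 && sum(cb) > 0, "both corpora must contain tokens")
  terms <- union(names(ca), names(cb))
  za <- stats::setNames(rep(0, length(terms)), terms); za[names(ca)] <- ca
  zb <- stats::setNames(rep(0, length(terms)), terms); zb[names(cb)] <- cb
  pooled <- (za / sum(za) + zb / sum(zb)) / 2 * (sum(za) + sum(zb))
  fit_a <- fit_sage(ca, pooled, max_iter = max_iter, tolerance = tolerance,
                    min_count = min_count, vocab_cap = vocab_cap)
  fit_b <- fit_sage(cb, pooled, max_iter = max_iter, tolerance = tolerance,
                    min_count = min_count, vocab_cap = vocab_cap)
  a <- top_terms(fit_a, k); a$target <- "a"
  b <- top_terms(fit_b, k); b$target <- "b"
  structure(list(a = a, b = b, fit_a = fit_a, fit_b = fit_b),
            class = "pv_keywords")
}

#' @export
print.pv_keywords <- function(x, ...) {
  cat("<pv_keywords>\n  salient in A:", paste(utils::head(x$a$term, 8L),
                                              collapse = ", "),
      "\n  salient in B:", paste(utils::head(x$b$term, 8L), collapse = ", "),
      "\n")
  invisible(x)
}
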