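zipf_background <- function(V = 200L, total = 1e5) {
  p <- 1 / seq_len(V); p <- p / sum(p)
  stats::setNames(round(p * total) + 1, sprintf("t%03d", seq_len(V)))
}

sample_target <- function(probs, n) {
  tc <- table(sample(names(probs), n, replace = TRUE, prob = probs))
  stats::setNames(as.numeric(tc), names(tc))
}

test_that("a proportional target yields a null fit", {
  bg <- zipf_background()
  fit <- fit_sage(bg * 3, bg)
  expect_lt(max(abs(fit$eta)), 0.05)
  expect_true(fit$converged)
  # background log-probabilities normalize
  expect_equal(sum(exp(fit$m)), 1, tolerance = 1e-12)
  # implied target distribution normalizes too
  expect_equal(sum(exp(fit$m + fit$eta) / sum(exp(fit$m + fit$eta))), 1)
})

test_that("a term generated at 10x its background rate attains the largest eta", {
  bg <- zipf_background()
  p <- bg / sum(bg)
  hits <- 0L
  for (s in 1:3) {
    set.seed(300 + s)
    tp <- p; tp["t050"] <- tp["t050"] * 10; tp <- tp / sum(tp)
    fit <- fit_sage(sample_target(tp, 20000), bg)
    hits <- hits + (top_terms(fit, 1)$term == "t050")
    expect_gt(fit$eta[["t050"]], 1.5)
  }
  expect_equal(hits, 3L)
})

test_that("the penalized objective is non-decreasing across EM rounds", {
  for (s in 1:5) {
    set.seed(400 + s)
    V <- sample(50:200, 1)
    bg <- zipf_background(V, total = sample(c(1e4, 1e5), 1))
    p <- bg / sum(bg)
    noisy <- p * exp(rnorm(V, 0, 0.5)); noisy <- noisy / sum(noisy)
    fit <- fit_sage(sample_target(noisy, 5000), bg)
    scale <- max(1, abs(fit$objective[1]))
    expect_true(all(diff(fit$objective) > -1e-8 * scale))
  }
})

test_that("the fitted deviations never lower the target log-likelihood below background", {
  set.seed(500)
  bg <- zipf_background(150)
  p <- bg / sum(bg)
  noisy <- p * exp(rnorm(150, 0, 0.7)); noisy <- noisy / sum(noisy)
  target <- sample_target(noisy, 8000)
  fit <- fit_sage(target, bg)
  tc <- stats::setNames(rep(0, length(fit$vocabulary)), fit$vocabulary)
  tc[intersect(names(target), fit$vocabulary)] <-
    target[intersect(names(target), fit$vocabulary)]
  loglik <- function(eta) {
    logp <- (fit$m + eta) - log(sum(exp(fit$m + eta)))
    sum(tc * logp)
  }
  expect_gte(loglik(fit$eta), loglik(rep(0, length(fit$eta))))
})

test_that("the self-tuned prior collapses noise deviations on null data", {
  set.seed(600)
  bg <- zipf_background(300, total = 1e5)
  target <- sample_target(bg / sum(bg), 20000)
  fit <- fit_sage(target, bg)
  expect_gt(mean(abs(fit$eta) < 1e-3), 0.9)
})

test_that("top_terms ranks by eta with lexicographic ties and truncation", {
  fit <- structure(list(vocabulary = c("b", "a", "c"),
                        m = stats::setNames(log(rep(1 / 3, 3)), c("b", "a", "c")),
                        eta = stats::setNames(c(0, 0, 0), c("b", "a", "c")),
                        tau = rep(1e-8, 3), n_iterations = 1L,
                        converged = TRUE, objective = 0),
                   class = "pv_sage_fit")
  expect_equal(nrow(top_terms(fit, 0)), 0L)
  expect_equal(top_terms(fit, 3)$term, c("a", "b", "c"))
  expect_warning(tt <- top_terms(fit, 10), "truncating")
  expect_equal(nrow(tt), 3L)
  # prefix property against a full-sort oracle
  set.seed(640)
  fit$eta <- stats::setNames(rnorm(3), fit$vocabulary)
  full <- fit$vocabulary[order(-fit$eta, fit$vocabulary)]
  expect_equal(top_terms(fit, 2)$term, full[1:2])
})

test_that("errors: empty target, disjoint vocabularies, bad counts", {
  bg <- zipf_background(50)
  expect_error(fit_sage(stats::setNames(numeric(0), character(0)), bg),
               class = "pv_error")
  expect_error(fit_sage(c(x = 1), c(y = 1), min_count = 5), class = "pv_error")
})

test_that("contrastive keywords: null symmetry, planted bigram, argument swap", {
  set.seed(700)
  vocab <- c("apple", "banana", "cherry", "date", "elder", "fig", "grape",
             "melon", "peach", "plum")
  mkdoc <- function(n) replicate(n, paste(sample(vocab, 8, TRUE),
                                          collapse = " "))
  a <- mkdoc(400)
  kw_null <- contrastive_keywords(a, a, k = 5)
  expect_lt(max(abs(kw_null$fit_a$eta)), 0.05)
  expect_lt(max(abs(kw_null$fit_b$eta)), 0.05)

  b <- mkdoc(400)
  b[1:80] <- paste(b[1:80], "weight gain")
  kw <- contrastive_keywords(a, b, k = 5)
  expect_true("weight gain" %in% kw$b$term)
  expect_false("weight gain" %in% kw$a$term)
  # swapping the corpora swaps the two lists
  kw_sw <- contrastive_keywords(b, a, k = 5)
  expect_equal(kw_sw$a$term, kw$b$term)
  expect_equal(kw_sw$b$term, kw$a$term)
})

test_that("stopword filtering drops function-word n-grams from the keyword space", {
  sw <- pv_stopwords()
  expect_true(all(c("the", "of", "and") %in% sw))
  set.seed(720)
  docs <- replicate(300, paste(sample(c("the", "of", "cake", "storm"), 6, TRUE),
                               collapse = " "))
  kw <- contrastive_keywords(docs, docs, k = 5)
  terms <- c(kw$a$term, kw$b$term)
  expect_false(any(vapply(strsplit(terms, " "), function(t)
    any(t %in% sw), logical(1))))
})
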