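test_that("generation is byte-identical under a fixed seed", {
  c1 <- generate_population(small_sim())
  c2 <- generate_population(small_sim())
  expect_identical(c1$posts, c2$posts)
  expect_identical(c1$truth, c2$truth)
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_corpus(c1, f1); write_corpus(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("corpus structure honours the config invariants", {
  cfg <- small_sim()
  corp <- generate_population(cfg)
  expect_equal(nrow(corp$truth), cfg$n_treatment + cfg$n_control)
  expect_equal(sum(corp$truth$is_treatment), cfg$n_treatment)
  expect_true(all(corp$posts$timestamp >= cfg$window_start &
                  corp$posts$timestamp <= cfg$window_end))
  tr <- corp$truth[corp$truth$is_treatment, ]
  expect_true(all(tr$disclosure_time > cfg$window_start &
                  tr$disclosure_time < cfg$window_end))
  expect_true(all(!is.na(tr$drug)))
  expect_true(all(is.na(corp$truth$drug[!corp$truth$is_treatment])))
  # exactly one intake-disclosure post per treated user
  disc <- corp$posts[grepl("^i took ", corp$posts$text), ]
  expect_equal(sort(disc$user_id), sort(tr$user_id))
  # posts sorted by user then time
  ord <- order(corp$posts$user_id, corp$posts$timestamp)
  expect_identical(ord, seq_len(nrow(corp$posts)))
})

test_that("write/read round-trip is lossless including the truth sidecar", {
  corp <- generate_population(small_sim(n_treatment = 30L, n_control = 30L))
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_identical(back$posts, corp$posts)
  expect_identical(back$users$user_id, corp$users$user_id)
  expect_equal(back$users$tenure_days, corp$users$tenure_days)
  expect_identical(back$truth$user_id, corp$truth$user_id)
  expect_identical(back$truth$is_treatment, corp$truth$is_treatment)
  expect_equal(back$truth$delta, corp$truth$delta)
  expect_equal(back$truth$baseline_rate, corp$truth$baseline_rate)
  # sidecar has exactly one truth row per user
  sidecar <- read.table(sub("\\.jsonl$", "_truth.tsv", path), sep = "\t",
                        header = TRUE)
  expect_equal(nrow(sidecar), nrow(corp$truth))
})

test_that("empty corpora and malformed lines are handled", {
  empty <- structure(list(posts = data.frame(post_id = character(0),
                                             user_id = character(0),
                                             timestamp = numeric(0),
                                             text = character(0),
                                             stringsAsFactors = FALSE),
                          users = data.frame(user_id = character(0),
                                             n_followers = numeric(0),
                                             tenure_days = numeric(0)),
                          truth = data.frame(user_id = character(0),
                                             is_treatment = logical(0),
                                             drug = character(0),
                                             disclosure_time = numeric(0),
                                             baseline_rate = numeric(0),
                                             delta = numeric(0),
                                             improved = logical(0),
                                             log_followers = numeric(0),
                                             n_posts_drawn = integer(0),
                                             tenure_days = numeric(0),
                                             p_treat = numeric(0)),
                          config = NULL), class = "pv_corpus")
  path <- tempfile(fileext = ".jsonl")
  write_corpus(empty, path)
  expect_equal(nrow(read_corpus(path)$posts), 0L)

  bad <- tempfile(fileext = ".jsonl")
  writeLines(c('{"post_id":"p1","user_id":"u1","timestamp":1,"text":"ok"}',
               "{not json"), bad)
  expect_error(read_corpus(bad), "line 2", class = "pv_parse_error")
})

test_that("empty planted lists leave only background and marker tokens in the text", {
  cfg <- small_sim(planted_terms_improved = character(0),
                   planted_terms_worsened = character(0),
                   inject_rate_improved = 0.5, inject_rate_worsened = 0.5)
  corp <- generate_population(cfg)
  mk <- unname(vapply(load_outcome_markers(), `[[`, character(1), 1L))
  allowed <- c(readLines(system.file("extdata", "background_vocab.txt",
                                     package = "pharmvig")), mk,
               "i", "took", cfg$drugs)
  toks <- unique(unlist(tokenize_all(corp$posts$text)))
  expect_true(all(toks %in% allowed))
})

test_that("zero confounder coefficients give no covariate-treatment correlation", {
  # Monte-Carlo: with gamma = 0 the empirical correlation between each
  # covariate and treatment should be near zero at n = 2000
  hits <- matrix(FALSE, nrow = 20L, ncol = 4L,
                 dimnames = list(NULL, c("log_followers", "n_posts_drawn",
                                         "tenure_days", "baseline_rate")))
  for (r in 1:20) {
    cfg <- sim_config(n_treatment = 1000L, n_control = 1000L,
                      posts_per_user_mean = 6,
                      confounder_coefs = c(0, 0, 0, 0), seed = 9000L + r)
    tr <- generate_population(cfg)$truth
    for (cv in colnames(hits))
      hits[r, cv] <- abs(cor(tr[[cv]], tr$is_treatment)) < 0.05
  }
  for (cv in colnames(hits))
    expect_gte(sum(hits[, cv]), 18L)
})

test_that("default confounding produces a real covariate imbalance", {
  # standardized mean difference of the planted confounder exceeds 0.1
  for (r in 1:3) {
    tr <- generate_population(sim_config(posts_per_user_mean = 6,
                                         seed = 700L + r))$truth
    x <- tr$log_followers
    t <- tr$is_treatment
    smd <- abs(mean(x[t]) - mean(x[!t])) /
      sqrt((var(x[t]) + var(x[!t])) / 2)
    expect_gt(smd, 0.1)
  }
})

test_that("hidden improvement ordering is recoverable from realized post rates", {
  # with improvement independent of baseline (slope 0) the realized
  # post-window symptom fraction must correlate negatively with delta
  cfg <- sim_config(n_treatment = 150L, n_control = 20L,
                    posts_per_user_mean = 60,
                    improvement_baseline_slope = 0,
                    improvement_effect_sd = 0.1, seed = 404L)
  corp <- generate_population(cfg)
  tr <- corp$truth[corp$truth$is_treatment, ]
  anchors <- stats::setNames(tr$disclosure_time, tr$user_id)
  prof <- outcome_profiles(corp, anchors)
  prof <- prof[prof$n_post >= 5, ]
  delta <- tr$delta[match(prof$user_id, tr$user_id)]
  rho <- cor(prof$post_depression, delta, method = "spearman")
  expect_lt(rho, -0.5)
})

test_that("infeasible assignment quotas raise a generation error", {
  cfg <- small_sim(n_treatment = 20L, n_control = 20L,
                   assignment_intercept = -40)
  expect_error(generate_population(cfg), "quota", class = "pv_generation_error")
})

test_that("config validation enforces the stated invariants", {
  expect_error(sim_config(inject_rate_improved = 1.5), "probabilities",
               class = "pv_validation_error")
  expect_error(sim_config(window_start = 10, window_end = 5),
               class = "pv_validation_error")
  expect_error(sim_config(vocab_size = 5), "vocab_size",
               class = "pv_validation_error")
  # YAML round trip
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_treatment = 10, n_control = 12, seed = 3), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_treatment, 10L)
  expect_error({
    yaml::write_yaml(list(bogus_field = 1), path)
    read_sim_config(path)
  }, "unknown", class = "pv_validation_error")
})
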