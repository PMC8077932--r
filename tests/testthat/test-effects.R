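test_that("stratum RTE arithmetic and the zero-denominator floor", {
  r <- stratum_rte(c(0.2, 0.2), c(0.2, 0.2), c(10, 10), c(10, 10))
  expect_equal(r$rte, 1)
  expect_false(r$floored)
  r2 <- stratum_rte(0.1, 0.2, 10, 10)
  expect_equal(r2$rte, 0.5)
  # p_control = 0 floored at 1 / (2 * control posts), flagged
  r3 <- stratum_rte(c(0.1, 0.3), c(0, 0), c(5, 5), c(12, 8))
  expect_true(r3$floored)
  expect_equal(r3$rte, 0.2 / (1 / 40))
  expect_error(stratum_rte(numeric(0), 0.1, numeric(0), 5),
               class = "pv_empty_arm_error")
})

make_rte_fixture <- function(rtes, n_t = 10L, n_c = 10L) {
  # one drug, one outcome per element is not enough: replicate across the
  # five outcomes so composites are well-defined
  do.call(rbind, lapply(seq_along(rtes), function(i) {
    data.frame(drug = "sertraline", stratum = i - 1L,
               outcome = outcome_names, p_treat = 0.1 * rtes[i],
               p_control = 0.1, rte = rtes[i], n_treat = n_t, n_control = n_c,
               floored = FALSE, stringsAsFactors = FALSE)
  }))
}

make_cohort_fixture <- function(n_strata_used, per_arm = 10L) {
  users <- expand.grid(stratum = seq_len(n_strata_used) - 1L,
                       arm = c("treatment", "control"),
                       i = seq_len(per_arm), stringsAsFactors = FALSE)
  users$user_id <- sprintf("%s_%02d_%02d", substr(users$arm, 1, 1),
                           users$stratum, users$i)
  scores <- stats::setNames((users$stratum + 0.5) / 100, users$user_id)
  trt <- stats::setNames(users$arm == "treatment", users$user_id)
  stratify(scores, trt, n_strata = 100)
}

test_that("cohort selection orders by improvement and respects k", {
  co <- make_cohort_fixture(2)
  tbl <- make_rte_fixture(c(0.5, 2.0))
  cp <- rank_strata_and_select(tbl, co, k = 1, shrink = 0)
  expect_equal(cp$k, 1L)
  # the improved cohort comes from the low-RTE stratum (stratum 0)
  expect_true(all(grepl("^t_00_", cp$most_improved)))
  expect_true(all(grepl("^t_01_", cp$least_improved)))
  expect_length(intersect(cp$most_improved, cp$least_improved), 0L)
  # invert flips the convention
  cpi <- rank_strata_and_select(tbl, co, k = 1, shrink = 0, invert = TRUE)
  expect_true(all(grepl("^t_01_", cpi$most_improved)))
})

test_that("ties are broken by stratum index and selection is deterministic", {
  co <- make_cohort_fixture(4)
  tbl <- make_rte_fixture(rep(1, 4))
  cp <- rank_strata_and_select(tbl, co, k = 2, shrink = 0)
  expect_equal(cp$ranking$stratum, 0:3)
  expect_true(all(grepl("^t_0[01]_", cp$most_improved)))
  cp2 <- rank_strata_and_select(tbl, co, k = 2, shrink = 0)
  expect_identical(cp$most_improved, cp2$most_improved)
})

test_that("k shrinks with a warning when strata are scarce, errors when none rankable", {
  co <- make_cohort_fixture(3)
  tbl <- make_rte_fixture(c(0.4, 1, 2.4))
  expect_warning(cp <- rank_strata_and_select(tbl, co, k = 10, shrink = 0),
                 "shrinking k")
  expect_equal(cp$k, 1L)
  expect_length(intersect(cp$most_improved, cp$least_improved), 0L)
  expect_error(rank_strata_and_select(tbl[0, ], co, k = 1), class = "pv_error")
})

test_that("stabilized ranking pulls one-user strata toward the trend", {
  co <- make_cohort_fixture(6)
  tbl <- make_rte_fixture(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.05))
  # give the extreme stratum one-user arms: its raw composite would win
  tbl$n_treat[tbl$stratum == 5] <- 1L
  tbl$n_control[tbl$stratum == 5] <- 1L
  raw <- rank_strata_and_select(tbl, co, k = 1, shrink = 0)
  stab <- rank_strata_and_select(tbl, co, k = 1, shrink = 5)
  expect_equal(raw$ranking$stratum[1], 5L)
  expect_false(stab$ranking$stratum[1] == 5L)
})

test_that("RTE from corpus rates matches a brute-force recount and is scale-free", {
  set.seed(33)
  cfg <- small_sim(n_treatment = 25L, n_control = 25L,
                   posts_per_user_mean = 20)
  corp <- generate_population(cfg)
  tr <- corp$truth
  anchors <- c(stats::setNames(tr$disclosure_time[tr$is_treatment],
                               tr$user_id[tr$is_treatment]),
               stats::setNames(rep(mean(tr$disclosure_time[tr$is_treatment]),
                                   sum(!tr$is_treatment)),
                               tr$user_id[!tr$is_treatment]))
  prof <- outcome_profiles(corp, anchors)
  # one synthetic stratum holding all 50 users
  scores <- stats::setNames(rep(0.5, nrow(tr)), tr$user_id)
  trt <- stats::setNames(tr$is_treatment, tr$user_id)
  co <- stratify(scores, trt, n_strata = 2)
  tbl <- rte_table(co, prof, stats::setNames(tr$drug, tr$user_id))
  mk <- load_outcome_markers()
  for (o in c("depression", "anxiety")) {
    recount <- function(uids) {
      mean(vapply(uids, function(u) {
        p <- corp$posts[corp$posts$user_id == u &
                        corp$posts$timestamp > anchors[[u]], ]
        mean(vapply(p$text, function(t) any(tokenize(t) %in% mk[[o]]),
                    logical(1)))
      }, numeric(1)))
    }
    t_ids <- prof$user_id[trt[prof$user_id] & prof$n_post > 0]
    c_ids <- prof$user_id[!trt[prof$user_id] & prof$n_post > 0]
    row <- tbl[tbl$outcome == o, ]
    expect_equal(row$p_treat, recount(t_ids))
    expect_equal(row$p_control, recount(c_ids))
    expect_equal(row$rte, row$p_treat / row$p_control)
  }
  # duplicating every post leaves the rates, hence the RTE, unchanged
  dup <- corp
  dup$posts <- rbind(corp$posts,
                     transform(corp$posts, post_id = paste0(post_id, "b")))
  prof2 <- outcome_profiles(dup, anchors)
  tbl2 <- rte_table(co, prof2, stats::setNames(tr$drug, tr$user_id))
  expect_equal(tbl2$rte, tbl$rte)
})
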