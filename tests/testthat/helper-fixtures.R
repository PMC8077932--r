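# shared fixture builders; everything is generated in code at test time

# hand-built corpus for unit tests that need exact control over posts
make_test_corpus <- function(posts, users = NULL) {
  stopifnot(all(c("post_id", "user_id", "timestamp", "text") %in% names(posts)))
  if (is.null(users)) {
    ids <- unique(posts$user_id)
    users <- data.frame(user_id = ids,
                        n_followers = seq(100, by = 50,
                                          length.out = length(ids)),
                        tenure_days = seq(300, by = 10,
                                          length.out = length(ids)),
                        stringsAsFactors = FALSE)
  }
  structure(list(posts = posts, users = users, truth = NULL, config = NULL),
            class = "pv_corpus")
}

# small three-drug lexicon written to a temp TSV
write_mini_lexicon <- function(rows = NULL) {
  rows <- rows %||% data.frame(
    generic = c("sertraline", "fluoxetine", "duloxetine"),
    brands = c("zoloft|lustral", "prozac", ""),
    family = c("SSRI", "SSRI", "SNRI"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compact generator settings for module-level tests
small_sim <- function(...) {
  args <- list(...)
  defaults <- list(n_treatment = 80L, n_control = 80L,
                   posts_per_user_mean = 15, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

outcome_names <- c("depression", "anxiety", "stress", "suicidal_ideation",
                   "psychosis")
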