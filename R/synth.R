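#' Configuration for the synthetic timeline generator
#'
#' Defines the study conditions emulated by [generate_population()]: a
#' treated arm of users who disclose intake of an antidepressant and a
#' control arm who never do, with covariate-confounded treatment assignment,
#' heterogeneous post-treatment symptomatic improvement, and cohort-specific
#' planted side-effect keywords.
#'
#' Treatment assignment is logistic in standardized pretreatment covariates
#' (log followers, activity, tenure, baseline symptom rate) with coefficients
#' `confounder_coefs`, then quota-resampled to hit the requested arm sizes.
#' The per-user improvement effect is
#' `delta = improvement_effect_mean +
#'          improvement_baseline_slope * (b - E[b]) + Normal(0, sd)`,
#' i.e. users with higher baseline symptom burden improve more (effect
#' modification by baseline severity); set the slope to 0 for improvement
#' independent of every covariate.
#'
#' @param n_treatment,n_control Arm sizes.
#' @param posts_per_user_mean Mean posts per user (shifted negative binomial,
#'   minimum `min_posts`).
#' @param vocab_size Number of background vocabulary words (Zipf-weighted).
#' @param confounder_coefs Named numeric vector of logistic assignment
#'   coefficients over standardized `(log_followers, activity, tenure,
#'   baseline)`.
#' @param assignment_intercept Intercept of the assignment model.
#' @param baseline_symptom_alpha,baseline_symptom_beta Beta prior for the
#'   per-user baseline per-post symptom probability.
#' @param improvement_effect_mean,improvement_effect_sd Mean and residual SD
#'   of the improvement effect delta for treated users.
#' @param improvement_baseline_slope Slope linking delta to the centred
#'   baseline rate.
#' @param inject_rate_improved,inject_rate_worsened Per-post probability that
#'   a post-treatment post of an above-median-delta (resp. below-median)
#'   treated user carries one planted side-effect term.
#' @param planted_terms_improved,planted_terms_worsened Planted term lists.
#' @param window_start,window_end Simulation window (seconds since epoch).
#' @param drugs Generic drug names assigned to treated users.
#' @param tokens_per_post_mean Mean background tokens per post.
#' @param min_posts Minimum posts per user.
#' @param seed Integer seed; the generator draws everything from one seeded
#'   stream in documented order, so equal configs give identical corpora.
#' @return A list of class `pv_sim_config`.
#' @export
sim_config <- function(n_treatment = 1000L,
                       n_control = 1000L,
                       posts_per_user_mean = 60,
                       vocab_size = 182L,
                       confounder_coefs = c(log_followers = 0.5, activity = 0,
                                            tenure = 0, baseline = 1.5),
                       assignment_intercept = 0,
                       baseline_symptom_alpha = 3,
                       baseline_symptom_beta = 9,
                       improvement_effect_mean = 0.10,
                       improvement_effect_sd = 0.05,
                       improvement_baseline_slope = 0.7,
                       inject_rate_improved = 0.15,
                       inject_rate_worsened = 0.15,
                       planted_terms_improved = c("fall asleep", "weight loss",
                                                  "good night", "lose weight",
                                                  "feeling better"),
                       planted_terms_worsened = c("want sleep", "weight gain",
                                                  "want eat", "chronic pain",
                                                  "panic attack"),
                       window_start = 1388534400,
                       window_end = 1518652800,
                       drugs = "sertraline",
                       tokens_per_post_mean = 8,
                       min_posts = 5L,
                       seed = 1L) {
  cfg <- list(n_treatment = as.integer(n_treatment),
              n_control = as.integer(n_control),
              posts_per_user_mean = posts_per_user_mean,
              vocab_size = as.integer(vocab_size),
              confounder_coefs = confounder_coefs,
              assignment_intercept = assignment_intercept,
              baseline_symptom_alpha = baseline_symptom_alpha,
              baseline_symptom_beta = baseline_symptom_beta,
              improvement_effect_mean = improvement_effect_mean,
              improvement_effect_sd = improvement_effect_sd,
              improvement_baseline_slope = improvement_baseline_slope,
              inject_rate_improved = inject_rate_improved,
              inject_rate_worsened = inject_rate_worsened,
              planted_terms_improved = planted_terms_improved,
              planted_terms_worsened = planted_terms_worsened,
              window_start = window_start,
              window_end = window_end,
              drugs = drugs,
              tokens_per_post_mean = tokens_per_post_mean,
              min_posts = as.integer(min_posts),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "pv_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pv_assert(cfg$n_treatment >= 0L && cfg$n_control >= 0L,
            "arm sizes must be non-negative")
  pv_assert(cfg$posts_per_user_mean > 0, "posts_per_user_mean must be positive")
  rates <- c(cfg$inject_rate_improved, cfg$inject_rate_worsened)
  pv_assert(all(rates >= 0 & rates <= 1),
            "injection rates must be probabilities in [0, 1]")
  pv_assert(cfg$window_start < cfg$window_end,
            "window_start must precede window_end")
  n_planted <- length(cfg$planted_terms_improved) +
    length(cfg$planted_terms_worsened)
  pv_assert(cfg$vocab_size >= n_planted + 10L,
            "vocab_size must be at least the number of planted terms + 10")
  pv_assert(cfg$baseline_symptom_alpha > 0 && cfg$baseline_symptom_beta > 0,
            "Beta prior parameters must be positive")
  pv_assert(length(cfg$confounder_coefs) == 4L,
            "confounder_coefs must have 4 entries (log_followers, activity, tenure, baseline)")
  invisible(TRUE)
}

#' Read a simulation config from YAML
#' @param path YAML file whose keys are `sim_config()` arguments.
#' @return A `pv_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    pv_stop(sprintf("unknown sim config field(s): %s", paste(bad, collapse = ", ")),
            "pv_validation_error")
  if (!is.null(raw$confounder_coefs))
    raw$confounder_coefs <- unlist(raw$confounder_coefs)
  do.call(sim_config, raw)
}

# background vocabulary: packaged common-word list, Zipf-weighted;
# extended with generated tokens when vocab_size exceeds the list.
background_vocab <- function(vocab_size) {
  words <- readLines(pv_extdata("background_vocab.txt"))
  words <- words[nzchar(words)]
  if (vocab_size > length(words))
    words <- c(words, sprintf("w%04d", seq_len(vocab_size - length(words))))
  words[seq_len(vocab_size)]
}

# first marker term per outcome: tokens the generator emits when a post is
# symptomatic, consumed downstream by the lexicon outcome scorer.
generator_markers <- function() {
  mk <- load_outcome_markers()
  vapply(mk, `[[`, character(1), 1L)
}

#' Generate a synthetic longitudinal corpus
#'
#' Draws the population described by a [sim_config()]: covariates, confounded
#' treatment assignment with quota resampling, per-user timelines of
#' timestamped posts with pre/post-treatment symptomatic marker tokens, one
#' "i took <drug>" disclosure post per treated user, and planted side-effect
#' terms in the post-treatment posts of treated users (list and rate chosen by
#' whether the user's improvement effect is above the treated median).
#'
#' @param config A `pv_sim_config`.
#' @return A list of class `pv_corpus` with components `posts` (data frame:
#'   `post_id`, `user_id`, `timestamp`, `text`), `users` (visible profile:
#'   `user_id`, `n_followers`, `tenure_days`), `truth` (hidden ground truth,
#'   kept for recovery tests and written to a separate sidecar file), and
#'   `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "pv_sim_config"))
  set.seed(config$seed)
  cfg <- config

  n_t <- cfg$n_treatment; n_c <- cfg$n_control
  need <- n_t + n_c
  mu_b <- cfg$baseline_symptom_alpha /
    (cfg$baseline_symptom_alpha + cfg$baseline_symptom_beta)
  sd_b <- sqrt(cfg$baseline_symptom_alpha * cfg$baseline_symptom_beta /
               ((cfg$baseline_symptom_alpha + cfg$baseline_symptom_beta)^2 *
                (cfg$baseline_symptom_alpha + cfg$baseline_symptom_beta + 1)))
  nb_mu <- max(cfg$posts_per_user_mean - cfg$min_posts, 0.1)
  nb_size <- 4
  nb_sd <- sqrt(nb_mu + nb_mu^2 / nb_size)
  ten_lo <- 100; ten_hi <- 2000

  # -- covariate draws + confounded assignment, quota-resampled ------------
  acc <- list(); got_t <- 0L; got_c <- 0L; draw_offset <- 0L
  max_batches <- 50L
  for (batch in seq_len(max_batches)) {
    if (got_t >= n_t && got_c >= n_c) break
    m <- max(200L, 2L * need)
    lf <- stats::rnorm(m, 5.5, 1.2)
    followers <- pmax(1, round(exp(lf)))
    nposts <- cfg$min_posts + stats::rnbinom(m, size = nb_size, mu = nb_mu)
    tenure <- stats::runif(m, ten_lo, ten_hi)
    b <- stats::rbeta(m, cfg$baseline_symptom_alpha, cfg$baseline_symptom_beta)
    z <- cbind(log_followers = (lf - 5.5) / 1.2,
               activity = (nposts - cfg$posts_per_user_mean) / nb_sd,
               tenure = (tenure - (ten_lo + ten_hi) / 2) /
                 sqrt((ten_hi - ten_lo)^2 / 12),
               baseline = (b - mu_b) / sd_b)
    p <- stats::plogis(cfg$assignment_intercept +
                       drop(z %*% unname(cfg$confounder_coefs)))
    trt <- stats::runif(m) < p
    keep_t <- which(trt)[seq_len(min(sum(trt), n_t - got_t))]
    keep_c <- which(!trt)[seq_len(min(sum(!trt), n_c - got_c))]
    keep <- sort(c(keep_t, keep_c))
    if (length(keep) > 0L) {
      acc[[length(acc) + 1L]] <- data.frame(
        draw = draw_offset + keep, is_treatment = trt[keep],
        n_followers = followers[keep], log_followers = lf[keep],
        n_posts_drawn = nposts[keep], tenure_days = tenure[keep],
        baseline_rate = b[keep], p_treat = p[keep],
        stringsAsFactors = FALSE)
      got_t <- got_t + length(keep_t); got_c <- got_c + length(keep_c)
    }
    draw_offset <- draw_offset + m
  }
  if (got_t < n_t || got_c < n_c)
    pv_stop(sprintf(paste0("could not fill treatment/control quotas after %d ",
                           "batches (got %d/%d treated, %d/%d control); ",
                           "assignment probabilities are too extreme"),
                    max_batches, got_t, n_t, got_c, n_c),
            "pv_generation_error")
  users <- do.call(rbind, acc)
  users <- users[order(users$draw), , drop = FALSE]
  n <- nrow(users)
  users$user_id <- sprintf("u%05d", seq_len(n))

  # -- treatment metadata and improvement effects --------------------------
  span <- cfg$window_end - cfg$window_start
  users$drug <- NA_character_
  users$disclosure_time <- NA_real_
  users$delta <- 0
  t_idx <- which(users$is_treatment)
  if (length(t_idx) > 0L) {
    users$drug[t_idx] <- as.character(sample(rep(cfg$drugs, 2L),
                                             length(t_idx), replace = TRUE))
    users$disclosure_time[t_idx] <-
      round(cfg$window_start + (0.3 + 0.4 * stats::runif(length(t_idx))) * span)
    users$delta[t_idx] <- cfg$improvement_effect_mean +
      cfg$improvement_baseline_slope * (users$baseline_rate[t_idx] - mu_b) +
      stats::rnorm(length(t_idx), 0, cfg$improvement_effect_sd)
  }
  med_delta <- if (length(t_idx) > 0L) stats::median(users$delta[t_idx]) else NA_real_
  users$improved <- NA
  users$improved[t_idx] <- users$delta[t_idx] > med_delta

  # -- posts ---------------------------------------------------------------
  n_i <- users$n_posts_drawn
  post_user <- rep(seq_len(n), n_i)
  N <- length(post_user)
  ts <- round(stats::runif(N, cfg$window_start, cfg$window_end))
  is_post_window <- users$is_treatment[post_user] &
    ts > users$disclosure_time[post_user] &
    !is.na(users$disclosure_time[post_user])
  rate <- users$baseline_rate[post_user]
  rate[is_post_window] <- clamp(users$baseline_rate[post_user] -
                                  users$delta[post_user], 0.01, 0.99)[is_post_window]

  vocab <- background_vocab(cfg$vocab_size)
  zipf <- (1 / seq_along(vocab)); zipf <- zipf / sum(zipf)
  L <- 1L + stats::rpois(N, max(cfg$tokens_per_post_mean - 1, 0.1))
  toks <- sample(vocab, sum(L), replace = TRUE, prob = zipf)
  toklist <- split(toks, factor(rep(seq_len(N), L), levels = seq_len(N)))
  names(toklist) <- NULL

  # symptomatic marker tokens, one per expressed outcome
  markers <- generator_markers()
  flags <- matrix(stats::runif(N * length(markers)) < rate, nrow = N)

  # planted side-effect phrases in post-treatment posts of treated users
  grp_improved <- is_post_window & users$improved[post_user] %in% TRUE
  grp_worsened <- is_post_window & users$improved[post_user] %in% FALSE
  inj <- stats::runif(N)
  phrase <- rep(NA_character_, N)
  if (length(cfg$planted_terms_improved) > 0L) {
    idx <- which(grp_improved & inj < cfg$inject_rate_improved)
    if (length(idx) > 0L)
      phrase[idx] <- sample(rep(cfg$planted_terms_improved, 2L),
                            length(idx), replace = TRUE)
  }
  if (length(cfg$planted_terms_worsened) > 0L) {
    idx <- which(grp_worsened & inj < cfg$inject_rate_worsened)
    if (length(idx) > 0L)
      phrase[idx] <- sample(rep(cfg$planted_terms_worsened, 2L),
                            length(idx), replace = TRUE)
  }

  # markers and phrases are spliced at random positions (phrases kept
  # contiguous) so post construction leaves no systematic token-order
  # signature at the post boundary
  needs_edit <- which(rowSums(flags) > 0L | !is.na(phrase))
  for (i in needs_edit) {
    t <- toklist[[i]]
    for (o in which(flags[i, ]))
      t <- append(t, markers[[o]], after = sample.int(length(t) + 1L, 1L) - 1L)
    if (!is.na(phrase[i]))
      t <- append(t, strsplit(phrase[i], " ", fixed = TRUE)[[1L]],
                  after = sample.int(length(t) + 1L, 1L) - 1L)
    toklist[[i]] <- t
  }
  text <- vapply(toklist, paste, character(1), collapse = " ")

  posts <- data.frame(user_id = users$user_id[post_user], timestamp = ts,
                      text = text, stringsAsFactors = FALSE)
  if (length(t_idx) > 0L) {
    disc <- data.frame(user_id = users$user_id[t_idx],
                       timestamp = users$disclosure_time[t_idx],
                       text = paste("i took", users$drug[t_idx]),
                       stringsAsFactors = FALSE)
    posts <- rbind(posts, disc)
  }
  posts <- posts[order(posts$user_id, posts$timestamp), , drop = FALSE]
  posts <- data.frame(post_id = sprintf("p%07d", seq_len(nrow(posts))),
                      posts, stringsAsFactors = FALSE)
  rownames(posts) <- NULL

  truth <- users[, c("user_id", "is_treatment", "drug", "disclosure_time",
                     "baseline_rate", "delta", "improved", "log_followers",
                     "n_posts_drawn", "tenure_days", "p_treat")]
  rownames(truth) <- NULL
  profile <- users[, c("user_id", "n_followers", "tenure_days")]
  rownames(profile) <- NULL

  structure(list(posts = posts, users = profile, truth = truth,
                 config = cfg),
            class = "pv_corpus")
}

#' @export
print.pv_corpus <- function(x, ...) {
  cat(sprintf("<pv_corpus> %d posts, %d users (%d treated)\n",
              nrow(x$posts), nrow(x$users),
              if (is.null(x$truth)) NA_integer_ else sum(x$truth$is_treatment)))
  invisible(x)
}

format_num17 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a corpus to disk
#'
#' The post stream is written as JSON-lines (one post per line with fields
#' `post_id`, `user_id`, `timestamp`, `text`). Visible user profiles and the
#' hidden ground-truth block go to sidecar TSV files (`<stem>_users.tsv`,
#' `<stem>_truth.tsv`) so the analysis pipeline can be run on the post stream
#' and profiles alone, blind to the truth sidecar.
#'
#' @param corpus A `pv_corpus`.
#' @param path Path of the JSON-lines file (conventionally `*.jsonl`).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "pv_corpus"))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (nrow(corpus$posts) > 0L)
    jsonlite::stream_out(corpus$posts, con, verbose = FALSE, digits = NA)
  stem <- sub("\\.jsonl$", "", path)
  up <- corpus$users
  up$tenure_days <- format_num17(up$tenure_days)
  pv_write_tsv(up, paste0(stem, "_users.tsv"))
  tr <- corpus$truth
  for (col in c("disclosure_time", "baseline_rate", "delta", "log_followers",
                "tenure_days", "p_treat"))
    tr[[col]] <- format_num17(tr[[col]])
  pv_write_tsv(tr, paste0(stem, "_truth.tsv"))
  invisible(path)
}

#' Read a corpus from disk
#'
#' Reads the JSON-lines post stream written by [write_corpus()] plus any
#' sidecar profile/truth files found next to it. A malformed line raises a
#' parse error naming the line number.
#'
#' @param path Path of the JSON-lines file.
#' @return A `pv_corpus` (with `truth = NULL` when no sidecar is present).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    posts <- data.frame(post_id = character(0), user_id = character(0),
                        timestamp = numeric(0), text = character(0),
                        stringsAsFactors = FALSE)
  } else {
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e)
        pv_stop(sprintf("malformed corpus line %d: %s", i, conditionMessage(e)),
                "pv_parse_error"))
      if (!all(c("post_id", "user_id", "timestamp", "text") %in% names(recs[[i]])))
        pv_stop(sprintf("malformed corpus line %d: missing fields", i),
                "pv_parse_error")
    }
    posts <- data.frame(
      post_id = vapply(recs, function(r) as.character(r$post_id), character(1)),
      user_id = vapply(recs, function(r) as.character(r$user_id), character(1)),
      timestamp = vapply(recs, function(r) as.numeric(r$timestamp), numeric(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      stringsAsFactors = FALSE)
  }
  stem <- sub("\\.jsonl$", "", path)
  users_path <- paste0(stem, "_users.tsv")
  truth_path <- paste0(stem, "_truth.tsv")
  users <- if (file.exists(users_path)) pv_read_tsv(users_path) else NULL
  truth <- if (file.exists(truth_path)) {
    tr <- pv_read_tsv(truth_path, colClasses = c(
      user_id = "character", is_treatment = "logical", drug = "character",
      disclosure_time = "numeric", baseline_rate = "numeric", delta = "numeric",
      improved = "logical", log_followers = "numeric", n_posts_drawn = "integer",
      tenure_days = "numeric", p_treat = "numeric"))
    tr
  } else NULL
  structure(list(posts = posts, users = users, truth = truth, config = NULL),
            class = "pv_corpus")
}
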