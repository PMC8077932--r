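OUTCOME_NAMES <- c("depression", "anxiety", "stress", "suicidal_ideation",
                   "psychosis")

#' Load the outcome marker-scorer configuration
#'
#' YAML mapping each of the five symptomatic outcomes (depression, anxiety,
#' stress, suicidal ideation, psychosis) to a marker-term list. A post is
#' positive for an outcome when it contains any marker term. The scorer
#' deliberately preserves the per-post five-binary-flags interface of trained
#' symptom classifiers so those can be plugged in unchanged.
#'
#' @param path YAML path, or `NULL` for the packaged configuration.
#' @return Named list of character vectors with exactly the five outcome keys.
#' @export
load_outcome_markers <- function(path = NULL) {
  path <- path %||% pv_extdata("outcome_markers.yaml")
  raw <- yaml::read_yaml(path)
  validate_outcome_markers(raw)
  lapply(raw, function(x) tolower(as.character(x)))[OUTCOME_NAMES]
}

validate_outcome_markers <- function(markers) {
  missing <- setdiff(OUTCOME_NAMES, names(markers))
  if (length(missing) > 0L)
    pv_stop(sprintf("scorer config is missing outcome(s): %s",
                    paste(missing, collapse = ", ")), "pv_validation_error")
  extra <- setdiff(names(markers), OUTCOME_NAMES)
  if (length(extra) > 0L)
    pv_stop(sprintf("scorer config has unknown outcome(s): %s",
                    paste(extra, collapse = ", ")), "pv_validation_error")
  invisible(TRUE)
}

#' Score posts for the five symptomatic outcomes
#'
#' @param texts Character vector of post texts.
#' @param markers Scorer configuration, see [load_outcome_markers()].
#' @return Logical matrix `length(texts) x 5`, columns named by outcome.
#' @export
score_posts <- function(texts, markers = NULL) {
  markers <- markers %||% load_outcome_markers()
  validate_outcome_markers(markers)
  padded <- pad_tokens(tokenize_all(texts))
  out <- matrix(FALSE, nrow = length(texts), ncol = length(OUTCOME_NAMES),
                dimnames = list(NULL, OUTCOME_NAMES))
  for (o in OUTCOME_NAMES) {
    for (term in markers[[o]]) {
      needle <- paste0(" ", paste(tokenize(term), collapse = " "), " ")
      out[, o] <- out[, o] | grepl(needle, padded, fixed = TRUE)
    }
  }
  out
}

#' Score a single post
#'
#' @param text Character scalar.
#' @inheritParams score_posts
#' @return Named logical vector of five outcome flags.
#' @export
score_post <- function(text, markers = NULL) {
  drop(score_posts(text, markers))
}

#' Pre/post outcome profile of one user
#'
#' Rates are positive posts divided by window posts per outcome, computed on
#' posts strictly before (`window = "pre"`) or strictly after
#' (`window = "post"`) the disclosure time; the disclosure post itself belongs
#' to neither window.
#'
#' @param corpus A `pv_corpus`.
#' @param user_id User id.
#' @param disclosure_time Anchor time.
#' @param window `"pre"` or `"post"`.
#' @param markers Scorer configuration.
#' @return List with `user_id`, `window`, `rates` (named numeric, 5 outcomes),
#'   `n_posts`, and `valid` (`FALSE` when the window is empty).
#' @export
outcome_profile <- function(corpus, user_id, disclosure_time,
                            window = c("pre", "post"), markers = NULL) {
  window <- match.arg(window)
  posts <- corpus$posts[corpus$posts$user_id == user_id, , drop = FALSE]
  sel <- if (window == "pre") posts$timestamp < disclosure_time
         else posts$timestamp > disclosure_time
  posts <- posts[sel, , drop = FALSE]
  if (nrow(posts) == 0L)
    return(list(user_id = user_id, window = window,
                rates = stats::setNames(rep(NA_real_, 5L), OUTCOME_NAMES),
                n_posts = 0L, valid = FALSE))
  flags <- score_posts(posts$text, markers)
  list(user_id = user_id, window = window,
       rates = colMeans(flags), n_posts = nrow(posts), valid = TRUE)
}

#' Pre- and post-window outcome rates for many users
#'
#' Vectorized profile builder used by the pipeline: one row per user with
#' pre/post post counts and per-outcome positive-post fractions.
#'
#' @param corpus A `pv_corpus`.
#' @param disclosure_times Named numeric vector (user -> anchor time).
#' @param markers Scorer configuration.
#' @return Data frame with columns `user_id`, `n_pre`, `n_post`,
#'   `pre_<outcome>` and `post_<outcome>` rates (NA for empty windows).
#' @export
outcome_profiles <- function(corpus, disclosure_times, markers = NULL) {
  markers <- markers %||% load_outcome_markers()
  uids <- names(disclosure_times)
  posts <- corpus$posts[corpus$posts$user_id %in% uids, , drop = FALSE]
  anchor <- disclosure_times[posts$user_id]
  flags <- score_posts(posts$text, markers)
  user_f <- factor(posts$user_id, levels = uids)
  out <- data.frame(user_id = uids, stringsAsFactors = FALSE)
  for (w in c("pre", "post")) {
    sel <- if (w == "pre") posts$timestamp < anchor else posts$timestamp > anchor
    n_w <- tapply(sel, user_f, sum)
    n_w[is.na(n_w)] <- 0L
    out[[paste0("n_", w)]] <- as.integer(n_w)
    for (o in OUTCOME_NAMES) {
      pos <- tapply(flags[, o] & sel, user_f, sum)
      pos[is.na(pos)] <- 0
      out[[paste0(w, "_", o)]] <- ifelse(n_w > 0, pos / pmax(n_w, 1L), NA_real_)
    }
  }
  out
}
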