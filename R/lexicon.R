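DRUG_FAMILIES <- c("SNRI", "SSRI", "tricyclic", "tetracyclic", "other")

#' Load an antidepressant drug lexicon
#'
#' Reads a lexicon mapping generic drug names to brand names and drug
#' families. The packaged default carries the 49 antidepressant and
#' augmentation generics studied in large-scale Twitter pharmacovigilance
#' work, with a small, deliberately non-exhaustive illustrative brand map
#' (extend it by supplying your own file).
#'
#' Accepted formats: TSV with columns `generic`, `brands` (pipe-separated,
#' may be empty) and `family`; or a JSON array of objects with the same
#' fields (`brands` as an array).
#'
#' @param path Path to a TSV or JSON lexicon; `NULL` (default) loads the
#'   packaged lexicon.
#' @return A data frame of class `pv_lexicon` with columns `generic`,
#'   `brands` (pipe-separated string) and `family`.
#' @export
load_lexicon <- function(path = NULL) {
  path <- path %||% pv_extdata("antidepressant_lexicon.tsv")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0L) {
      df <- data.frame(generic = character(0), brands = character(0),
                       family = character(0), stringsAsFactors = FALSE)
    } else {
      brands <- vapply(raw$brands, function(b) paste(unlist(b), collapse = "|"),
                       character(1))
      df <- data.frame(generic = raw$generic, brands = brands,
                       family = raw$family %||% rep("other", nrow(raw)),
                       stringsAsFactors = FALSE)
    }
  } else {
    df <- tryCatch(pv_read_tsv(path, colClasses = "character"),
                   error = function(e) {
                     # an empty file (no header) is a valid empty lexicon
                     data.frame(generic = character(0), brands = character(0),
                                family = character(0), stringsAsFactors = FALSE)
                   })
  }
  if (nrow(df) == 0L) {
    out <- data.frame(generic = character(0), brands = character(0),
                      family = character(0), stringsAsFactors = FALSE)
    class(out) <- c("pv_lexicon", "data.frame")
    return(out)
  }
  pv_assert(all(c("generic", "family") %in% names(df)),
            "lexicon must have columns generic, brands, family")
  if (is.null(df$brands)) df$brands <- ""
  df$brands[is.na(df$brands)] <- ""
  df$generic <- tolower(trimws(df$generic))
  df$brands <- tolower(trimws(df$brands))
  df$family <- trimws(df$family)
  df$family[!nzchar(df$family)] <- "other"
  pv_assert(all(nzchar(df$generic)), "lexicon generic names must be non-empty")
  dup <- unique(df$generic[duplicated(df$generic)])
  if (length(dup) > 0L)
    pv_stop(sprintf("duplicate generic name(s) in lexicon: %s",
                    paste(dup, collapse = ", ")), "pv_validation_error")
  bad <- setdiff(unique(df$family), DRUG_FAMILIES)
  if (length(bad) > 0L)
    pv_stop(sprintf("unknown drug family label(s): %s",
                    paste(bad, collapse = ", ")), "pv_validation_error")
  out <- df[, c("generic", "brands", "family")]
  rownames(out) <- NULL
  class(out) <- c("pv_lexicon", "data.frame")
  out
}

#' Flatten a lexicon into a term -> generic lookup table
#'
#' @param lexicon A `pv_lexicon`.
#' @return Data frame with columns `term` (generic or brand, lowercase) and
#'   `generic`.
#' @export
lexicon_terms <- function(lexicon) {
  stopifnot(inherits(lexicon, "pv_lexicon"))
  if (nrow(lexicon) == 0L)
    return(data.frame(term = character(0), generic = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(lexicon)), function(i) {
    brands <- strsplit(lexicon$brands[i], "|", fixed = TRUE)[[1L]]
    brands <- brands[nzchar(brands)]
    data.frame(term = c(lexicon$generic[i], brands),
               generic = lexicon$generic[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out$term), , drop = FALSE]
}

# word-boundary regex for a lexicon term; boundaries are defined against the
# token alphabet [a-z0-9] so "sertralineish" does not match "sertraline",
# while hyphenated generics match as printed.
term_pattern <- function(term) {
  esc <- gsub("([][.\\\\+*?^$(){}=!<>|:#-])", "\\\\\\1", term, perl = TRUE)
  paste0("(?<![a-z0-9])", esc, "(?![a-z0-9])")
}

#' Match drug mentions in a text
#'
#' Case-insensitive, word-boundary matching of every lexicon term (generic or
#' brand). When a longer term overlaps a shorter one at the same location the
#' longest match wins; identical terms never yield overlapping spans.
#'
#' @param text Character scalar.
#' @param lexicon A `pv_lexicon`.
#' @param post_id Optional identifier copied into the result.
#' @return Data frame with columns `post_id`, `matched_term`, `generic_name`,
#'   `start`, `end`. Spans are 0-based, half-open over characters of `text`.
#' @export
match_mentions <- function(text, lexicon, post_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(post_id = character(0), matched_term = character(0),
                      generic_name = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  terms <- lexicon_terms(lexicon)
  if (nrow(terms) == 0L || is.na(text) || !nzchar(text)) return(empty)
  low <- tolower(text)
  cand <- lapply(seq_len(nrow(terms)), function(i) {
    m <- gregexpr(term_pattern(terms$term[i]), low, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    len <- attr(m, "match.length")
    data.frame(matched_term = terms$term[i], generic_name = terms$generic[i],
               start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + as.integer(len),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # longest-match-wins overlap resolution
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$matched_term), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(post_id = rep(post_id, nrow(out)), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.pv_lexicon <- function(x, ...) {
  cat(sprintf("<pv_lexicon> %d generics, %d brand terms, families: %s\n",
              nrow(x),
              sum(nzchar(unlist(strsplit(x$brands, "|", fixed = TRUE)))),
              paste(sort(unique(x$family)), collapse = ", ")))
  invisible(x)
}
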