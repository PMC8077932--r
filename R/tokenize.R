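#' Tokenize text into lowercase word tokens
#'
#' Lowercases, strips punctuation and splits on whitespace. Tokens are runs of
#' ASCII letters and digits; everything else is a separator. Deterministic and
#' idempotent: `tokenize(paste(tokenize(x), collapse = " "))` equals
#' `tokenize(x)`.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Fell asleep, again!")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- trimws(gsub("[^a-z0-9]+", " ", tolower(text)))
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1L]]
}

#' Tokenize a vector of texts
#'
#' Vectorized companion of [tokenize()]; returns a list of token vectors.
#'
#' @param texts Character vector.
#' @return List of character vectors, one per input text.
#' @export
tokenize_all <- function(texts) {
  stopifnot(is.character(texts))
  x <- trimws(gsub("[^a-z0-9]+", " ", tolower(texts)))
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

#' Contiguous n-grams of a token sequence
#'
#' @param tokens Character vector of tokens.
#' @param n N-gram order (>= 1).
#' @return Character vector of `max(0, length(tokens) - n + 1)` n-grams,
#'   tokens joined by single spaces.
#' @examples
#' ngrams(c("fall", "asleep"), 2)
#' @export
ngrams <- function(tokens, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    pv_stop("n-gram order must be a single integer >= 1", "pv_argument_error")
  n <- as.integer(n)
  L <- length(tokens)
  if (L < n) return(character(0))
  if (n == 1L) return(as.character(tokens))
  idx <- seq_len(L - n + 1L)
  out <- tokens[idx]
  for (j in 2:n) out <- paste(out, tokens[idx + j - 1L])
  out
}

#' N-gram counts over a set of documents
#'
#' Tokenizes each document and tallies n-grams of the requested orders into a
#' single named count vector (a shared multinomial over all orders).
#'
#' @param texts Character vector of documents.
#' @param orders Integer vector of n-gram orders, default `c(1, 2)`.
#' @return Named numeric vector of counts.
#' @export
ngram_counts <- function(texts, orders = c(1L, 2L)) {
  toks <- tokenize_all(texts)
  grams <- unlist(lapply(orders, function(n) {
    unlist(lapply(toks, ngrams, n = n), use.names = FALSE)
  }), use.names = FALSE)
  if (length(grams) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(grams)
  stats::setNames(as.numeric(tab), names(tab))
}

# Normalize a token vector into a padded string " t1 t2 ... " so that
# multiword phrases can be located with fixed-string matching.
pad_tokens <- function(token_list) {
  vapply(token_list, function(t) {
    if (length(t) == 0L) "  " else paste0(" ", paste(t, collapse = " "), " ")
  }, character(1))
}
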