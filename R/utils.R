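#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' All validation and pipeline failures raise conditions inheriting from
#' "pv_error" so callers can distinguish them from programming errors.
#' @noRd
pv_stop <- function(message, class = "pv_error", data = list()) {
  cond <- structure(
    class = c(class, "pv_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

pv_assert <- function(ok, message, class = "pv_validation_error") {
  if (!isTRUE(ok)) pv_stop(message, class = class)
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Path to a packaged data file
#' @noRd
pv_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pharmvig")
  pv_assert(nzchar(path), sprintf("packaged data file not found: %s", file))
  path
}

# Simple stage logger: collects timestamped lines; optionally echoes.
pv_logger <- function(verbose = FALSE) {
  lines <- character(0)
  list(
    log = function(fmt, ...) {
      line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
      lines <<- c(lines, line)
      if (verbose) message(line)
      invisible(line)
    },
    lines = function() lines
  )
}

# write.table wrapper fixing the conventions used for every exported table
pv_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

pv_read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}
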