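# Internal helpers shared across modules.

#' Normalise gene symbols
#'
#' Upper-cases and trims symbols so that identifiers from different sources
#' ("s100a8", "S100A8 ") intersect correctly.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalised symbols.
#' @export
norm_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# stop() with the calling function's name stripped from the message chain
.fail <- function(...) stop(..., call. = FALSE)

.assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .fail(name, " must be a single finite number")
  }
  if (strict_min && x <= min) .fail(name, " must be > ", min)
  if (!strict_min && x < min) .fail(name, " must be >= ", min)
  invisible(x)
}

# deterministic derived seed for a named pipeline sub-stream; keeps all
# derived seeds well inside 32-bit integer range
.substream_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
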