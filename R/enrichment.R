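# Gene-set over-representation: upper-tail hypergeometric test of a DEG
# set against a GMT collection, conditioned on the measured universe.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' Symbols are normalised; empty sets are dropped.
#'
#' @param path GMT file path.
#' @return named list of character vectors; each element carries its
#'   source description in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) next
    genes <- unique(norm_symbols(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) next
    s <- sort(genes)
    attr(s, "description") <- f[2]
    sets[[f[1]]] <- s
  }
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each pathway with `K` measured members, tests whether the overlap
#' `x` between the DEG set (size `n`) and the pathway exceeds what uniform
#' draws from the universe (size `N`) would give:
#' `p = sum_{k >= x} C(K,k) C(N-K, n-k) / C(N,n)` (one-sided,
#' over-representation only). Significance is `p <= 0.05` on the raw p, as
#' is conventional for screening; a Benjamini-Hochberg column is emitted
#' for information.
#'
#' The universe should be the genes measured in the dataset (matrix rows),
#' not the union of the collection, so that the null conditions on what
#' could have been called.
#'
#' @param degs character vector of DEG symbols (must be a subset of
#'   `universe`).
#' @param universe character vector of measured symbols.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param alpha significance level on the raw p (default 0.05, inclusive).
#' @return data.frame `pathway`, `overlap`, `set_size`, `deg_count`,
#'   `universe_size`, `p`, `bh_fdr`, `significant`, sorted by `p`
#'   ascending with ties broken by pathway label.
#' @examples
#' enrich(c("A", "B"), LETTERS[1:10], list(S1 = c("A", "B", "C")))
#' @export
enrich <- function(degs, universe, collection, alpha = 0.05) {
  degs <- unique(norm_symbols(degs))
  universe <- unique(norm_symbols(universe))
  if (!length(collection)) .fail("empty gene-set collection")
  stray <- setdiff(degs, universe)
  if (length(stray)) {
    .fail("DEGs not in universe: ", paste(stray, collapse = ", "))
  }
  N <- length(universe)
  n <- length(degs)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(norm_symbols(collection[[nm]]), universe)
    K <- length(set)
    x <- length(intersect(set, degs))
    # upper tail P(X >= x); x = 0 gives p = 1
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, overlap = x, set_size = K, deg_count = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  out$bh_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  rownames(out) <- NULL
  out
}

#' Pathways significant in every dataset
#'
#' Intersects the significant pathway sets of per-dataset enrichment
#' results; the per-dataset significant sets are attached as an attribute
#' for reporting.
#'
#' @param per_dataset named list of [enrich()] result data.frames
#'   (>= 2 datasets).
#' @return sorted character vector of pathways significant everywhere,
#'   with `attr(, "per_dataset")` listing each dataset's significant set.
#' @export
common_significant_pathways <- function(per_dataset) {
  if (length(per_dataset) < 2) .fail("need >= 2 datasets")
  sig <- lapply(per_dataset, function(res) res$pathway[res$significant])
  common <- sort(Reduce(intersect, sig))
  attr(common, "per_dataset") <- sig
  common
}
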