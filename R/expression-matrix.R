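# ExpressionMatrix: genes x samples log2-scale values plus a phenotype map.
# The common currency of all statistics stages.

#' Construct an expression matrix with phenotype labels
#'
#' Bundles a numeric genes-by-samples matrix (log2 scale) with a
#' sample-to-group phenotype map. Duplicate gene symbols are collapsed by
#' keeping, for each symbol, the row with the largest interquartile range
#' (the conventional deterministic probe-to-gene reduction).
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample identifiers). Values must be finite and
#'   on log2 scale.
#' @param phenotype named character vector or factor mapping every sample
#'   (names) to a group label, or a data.frame with columns `sample`,
#'   `group`.
#' @param collapse collapse duplicate gene symbols by IQR-max (default TRUE).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (matrix, unique upper-cased symbols) and `phenotype`
#'   (named character vector aligned with `colnames(values)`).
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("A", "B"), paste0("s", 1:4)))
#' ph <- setNames(rep(c("case", "ctrl"), each = 2), paste0("s", 1:4))
#' em <- expression_matrix(m, ph)
#' @export
expression_matrix <- function(values, phenotype, collapse = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    .fail("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    .fail("values must have gene rownames and sample colnames")
  }
  if (!all(is.finite(values))) .fail("expression values must be finite")
  if (is.data.frame(phenotype)) {
    if (!all(c("sample", "group") %in% names(phenotype))) {
      .fail("phenotype data.frame needs columns 'sample' and 'group'")
    }
    phenotype <- stats::setNames(as.character(phenotype$group),
                                 phenotype$sample)
  }
  phenotype <- stats::setNames(as.character(phenotype), names(phenotype))
  missing_ph <- setdiff(colnames(values), names(phenotype))
  if (length(missing_ph)) {
    .fail("samples without phenotype label: ",
          paste(missing_ph, collapse = ", "))
  }
  phenotype <- phenotype[colnames(values)]
  rownames(values) <- norm_symbols(rownames(values))
  if (anyDuplicated(rownames(values))) {
    if (!collapse) .fail("duplicate gene symbols present")
    values <- collapse_duplicate_genes(values)
  }
  structure(list(values = values, phenotype = phenotype),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$phenotype)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Collapse duplicate gene symbols by maximum interquartile range
#'
#' For each duplicated rowname keeps the single row with the largest IQR
#' across samples; ties break on row order for determinism.
#'
#' @param values numeric matrix with (possibly duplicated) gene rownames.
#' @return matrix with unique rownames.
#' @export
collapse_duplicate_genes <- function(values) {
  iqr <- apply(values, 1L, stats::IQR)
  ord <- order(rownames(values), -iqr)
  values <- values[ord, , drop = FALSE]
  values[!duplicated(rownames(values)), , drop = FALSE]
}

#' Read an expression matrix and its phenotype map from TSV
#'
#' The expression file has a `gene` first column and one column per sample;
#' the phenotype file has columns `sample` and `group`. Gene symbols are
#' upper-cased and duplicates collapsed by IQR-max.
#'
#' @param path expression TSV path.
#' @param phenotype_path phenotype TSV path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, phenotype_path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene") .fail("first column of ", path, " must be 'gene'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    .fail("non-numeric expression column '", names(df[-1])[bad], "' in ", path)
  }
  rownames(vals) <- df$gene
  ph <- .read_tsv(phenotype_path)
  if (!all(c("sample", "group") %in% names(ph))) {
    .fail(phenotype_path, " needs columns 'sample' and 'group'")
  }
  expression_matrix(vals, ph)
}

#' Write an expression matrix (and optionally its phenotype map) to TSV
#'
#' @param em an [expression_matrix()].
#' @param path expression TSV path.
#' @param phenotype_path optional phenotype TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path, phenotype_path = NULL) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE)
  .write_tsv(df, path)
  if (!is.null(phenotype_path)) {
    .write_tsv(data.frame(sample = names(em$phenotype),
                          group = unname(em$phenotype)), phenotype_path)
  }
  invisible(path)
}
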