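# Cross-dataset biomarker logic: DEG-set intersection, miRNA target
# mapping, and the per-gene average expressions that seed the pathway
# models.

#' Bundle a DEG set with its provenance
#'
#' @param genes character vector of DEG symbols (normalised, deduplicated).
#' @param dataset_id dataset identifier.
#' @param disease disease label, e.g. `"psoriasis"` or `"cSCC"`.
#' @param contrast contrast description string.
#' @return a `deg_set` list.
#' @export
deg_set <- function(genes, dataset_id = "dataset", disease = NA_character_,
                    contrast = NA_character_) {
  structure(list(dataset_id = dataset_id, disease = disease,
                 contrast = contrast,
                 genes = sort(unique(norm_symbols(genes)))),
            class = "deg_set")
}

#' Intersect DEG sets across datasets
#'
#' Exact set intersection after symbol normalisation; commutative,
#' associative and idempotent.
#'
#' @param sets list of at least two [deg_set()]s or character vectors.
#' @return sorted character vector of common symbols.
#' @examples
#' intersect_degs(list(c("A", "B"), c("b", "C")))  # "B"
#' @export
intersect_degs <- function(sets) {
  if (length(sets) < 2) .fail("need at least 2 DEG sets to intersect")
  gene_lists <- lapply(sets, function(s) {
    if (inherits(s, "deg_set")) s$genes else unique(norm_symbols(s))
  })
  sort(Reduce(intersect, gene_lists))
}

#' Map miRNAs to the union of their target genes
#'
#' Local replacement for a target-database query: joins the supplied
#' miRNA identifiers against a mapping table. miRNAs absent from the map
#' are reported via a warning and an attribute, not an error.
#'
#' @param mirnas character vector of miRNA identifiers.
#' @param map data.frame with columns `mirna`, `gene`
#'   (see [generate_mirna_map()] or [read_mirna_map()]).
#' @return character vector: union of target symbols, with unmapped
#'   miRNAs in `attr(, "unmapped")`.
#' @export
map_mirna_targets <- function(mirnas, map) {
  if (!all(c("mirna", "gene") %in% names(map))) {
    .fail("map needs columns 'mirna' and 'gene'")
  }
  mirnas <- unique(mirnas)
  unmapped <- setdiff(mirnas, map$mirna)
  if (length(unmapped)) {
    warning("miRNAs absent from the target map: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  targets <- sort(unique(norm_symbols(map$gene[map$mirna %in% mirnas])))
  attr(targets, "unmapped") <- unmapped
  targets
}

#' Read / write a miRNA target map as TSV
#'
#' @param path TSV path with columns `mirna`, `gene`.
#' @return data.frame `mirna`, `gene`.
#' @export
read_mirna_map <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("mirna", "gene") %in% names(df))) {
    .fail(path, " needs columns 'mirna' and 'gene'")
  }
  df$gene <- norm_symbols(df$gene)
  df
}

#' @rdname read_mirna_map
#' @param map data.frame `mirna`, `gene`.
#' @export
write_mirna_map <- function(map, path) .write_tsv(map, path)

#' Average expression of genes over disease samples, pooled across datasets
#'
#' For each requested gene, the mean of its log2 values over all samples
#' whose phenotype is in `disease_groups`, pooling samples across all
#' matrices that measure the gene (not averaging per-dataset means). Genes
#' absent from every matrix are reported in `attr(, "skipped")`.
#'
#' @param matrices list of [expression_matrix()] objects.
#' @param genes symbols to average.
#' @param disease_groups phenotype labels defining the disease samples.
#' @param disease disease label recorded in the output.
#' @return data.frame `gene`, `disease`, `avg_expr` (an
#'   AvgExpressionTable), plus a `skipped` attribute.
#' @export
average_expression <- function(matrices, genes, disease_groups,
                               disease = NA_character_) {
  if (inherits(matrices, "ExpressionMatrix")) matrices <- list(matrices)
  genes <- unique(norm_symbols(genes))
  sums <- stats::setNames(numeric(length(genes)), genes)
  ns <- stats::setNames(integer(length(genes)), genes)
  for (em in matrices) {
    cols <- which(em$phenotype %in% disease_groups)
    if (!length(cols)) next
    found <- intersect(genes, rownames(em$values))
    if (!length(found)) next
    block <- em$values[found, cols, drop = FALSE]
    sums[found] <- sums[found] + rowSums(block)
    ns[found] <- ns[found] + ncol(block)
  }
  skipped <- genes[ns == 0]
  if (length(skipped)) {
    warning("genes absent from all matrices: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  keep <- ns > 0
  out <- data.frame(gene = genes[keep], disease = disease,
                    avg_expr = sums[keep] / ns[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Read an average-expression table
#'
#' Reads a TSV with columns `gene`, `disease`, `avg_expr`, such as the
#' shipped table of IL-17 pathway DEG average expressions used to seed the
#' pathway models (see [il17_avg_expression()]).
#'
#' @param path TSV path.
#' @return data.frame `gene`, `disease`, `avg_expr`.
#' @export
read_avg_expression <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("gene", "disease", "avg_expr") %in% names(df))) {
    .fail(path, " needs columns 'gene', 'disease', 'avg_expr'")
  }
  df$gene <- norm_symbols(df$gene)
  df
}

#' Shipped average-expression table for the IL-17 pathway DEGs
#'
#' The per-disease average log2 expressions of the psoriasis and cSCC DEGs
#' enriched in the IL-17 signalling pathway, as used to seed the shipped
#' pathway models.
#'
#' @param disease optional filter, `"psoriasis"` or `"cSCC"`.
#' @return data.frame `gene`, `disease`, `avg_expr`.
#' @export
il17_avg_expression <- function(disease = NULL) {
  df <- read_avg_expression(system.file("extdata", "avg_expr_table5.tsv",
                                        package = "il17path",
                                        mustWork = TRUE))
  if (!is.null(disease)) df <- df[df$disease == disease, , drop = FALSE]
  df
}
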