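# Synthetic expression data with known ground truth.
#
# The generator emulates the statistical structure the DE stage assumes:
# gene-level log2 intensities (microarray-like) or negative-binomial counts
# (RNA-seq-like), with a planted fraction of differential genes shifted in
# the first (disease) group.

#' Specify a synthetic expression dataset
#'
#' @param n_genes number of genes (positive integer).
#' @param groups named integer vector of per-group sample counts, e.g.
#'   `c(lesional = 5, normal = 5)`. Every group needs >= 2 samples so that
#'   within-group variance is estimable. Planted differential genes are
#'   shifted in the first group.
#' @param deg_fraction fraction of genes planted as differential, in `[0, 1]`.
#' @param effect_size log2-scale mean shift of planted genes (each planted
#'   gene is shifted up or down with equal probability).
#' @param sigma per-gene Gaussian noise SD on log2 scale (positive).
#' @param baseline_mean log2-scale grand mean.
#' @param seed integer seed; identical specs give bit-identical data.
#' @return a `synth_spec` list, validated.
#' @export
synth_spec <- function(n_genes, groups, deg_fraction = 0.1, effect_size = 1,
                       sigma = 0.5, baseline_mean = 7, seed = 1L) {
  .assert_scalar_number(n_genes, "n_genes", min = 1)
  if (n_genes != round(n_genes)) .fail("n_genes must be an integer")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    .fail("groups must be a named vector of sample counts")
  }
  if (any(groups < 2)) .fail("all group sample counts must be >= 2")
  .assert_scalar_number(deg_fraction, "deg_fraction", min = 0)
  if (deg_fraction > 1) .fail("deg_fraction must be in [0, 1]")
  .assert_scalar_number(effect_size, "effect_size")
  .assert_scalar_number(sigma, "sigma", min = 0, strict_min = TRUE)
  .assert_scalar_number(baseline_mean, "baseline_mean")
  spec <- list(n_genes = as.integer(n_genes),
               groups = vapply(groups, as.integer, integer(1)),
               deg_fraction = deg_fraction, effect_size = effect_size,
               sigma = sigma, baseline_mean = baseline_mean,
               seed = as.integer(seed))
  class(spec) <- "synth_spec"
  spec
}

# shared layout: gene names, sample names, planted truth table
.synth_layout <- function(spec) {
  n_deg <- as.integer(round(spec$deg_fraction * spec$n_genes))
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  samples <- unlist(lapply(seq_along(spec$groups), function(i) {
    sprintf("%s_%d", names(spec$groups)[i], seq_len(spec$groups[i]))
  }))
  group_of <- rep(names(spec$groups), spec$groups)
  is_deg <- c(rep(TRUE, n_deg), rep(FALSE, spec$n_genes - n_deg))
  sign <- numeric(spec$n_genes)
  if (n_deg > 0) sign[seq_len(n_deg)] <- ifelse(stats::runif(n_deg) < 0.5, -1, 1)
  truth <- data.frame(gene = genes, is_deg = is_deg,
                      true_shift = sign * spec$effect_size,
                      stringsAsFactors = FALSE)
  list(genes = genes, samples = samples, group_of = group_of, truth = truth)
}

#' Generate a microarray-like log2 intensity matrix with planted DEGs
#'
#' Values are `baseline_mean + shift + N(0, sigma^2)`, where the shift
#' applies only to planted differential genes in the first group. No
#' probe-level structure is simulated; the pipeline starts at gene level.
#'
#' @param spec a [synth_spec()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene`, `is_deg`, `true_shift`).
#' @examples
#' sp <- synth_spec(200, c(lesional = 5, normal = 5), effect_size = 2)
#' d <- generate_microarray(sp)
#' table(d$truth$is_deg)
#' @export
generate_microarray <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(.substream_seed(spec$seed, 1L))
  lay <- .synth_layout(spec)
  n_s <- length(lay$samples)
  vals <- matrix(stats::rnorm(spec$n_genes * n_s, spec$baseline_mean,
                              spec$sigma),
                 spec$n_genes, n_s, dimnames = list(lay$genes, lay$samples))
  in_first <- lay$group_of == names(spec$groups)[1]
  vals[, in_first] <- vals[, in_first] + lay$truth$true_shift
  ph <- stats::setNames(lay$group_of, lay$samples)
  list(matrix = expression_matrix(vals, ph), truth = lay$truth)
}

#' Generate RNA-seq-like negative-binomial counts with planted DEGs
#'
#' Counts are negative binomial with group mean `2^(baseline + shift)` and
#' the given dispersion (`var = mu + dispersion * mu^2`); the returned
#' expression matrix is on log2(count + 1) scale for the shared DE stage.
#'
#' @param spec a [synth_spec()]; `sigma` is unused for counts.
#' @param dispersion negative-binomial dispersion (> 0); values near zero
#'   approach Poisson sampling.
#' @return list with `matrix` (log2(count+1) [expression_matrix()]),
#'   `counts` (integer matrix) and `truth`.
#' @export
generate_counts <- function(spec, dispersion = 0.1) {
  stopifnot(inherits(spec, "synth_spec"))
  .assert_scalar_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  set.seed(.substream_seed(spec$seed, 2L))
  lay <- .synth_layout(spec)
  n_s <- length(lay$samples)
  in_first <- lay$group_of == names(spec$groups)[1]
  mu <- matrix(2^spec$baseline_mean, spec$n_genes, n_s,
               dimnames = list(lay$genes, lay$samples))
  mu[, in_first] <- 2^(spec$baseline_mean + lay$truth$true_shift)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  ph <- stats::setNames(lay$group_of, lay$samples)
  list(matrix = expression_matrix(log2(counts + 1), ph),
       counts = counts, truth = lay$truth)
}

#' Generate a toy miRNA-to-target mapping
#'
#' Each miRNA is assigned a uniform random subset of the gene pool, drawn
#' without replacement; deterministic for a fixed seed.
#'
#' @param n_mirnas number of miRNAs (>= 0).
#' @param targets_per_mirna targets per miRNA (<= `length(gene_pool)`).
#' @param gene_pool character vector of candidate target symbols.
#' @param seed integer seed.
#' @return data.frame with columns `mirna`, `gene` (a MirnaTargetMap).
#' @export
generate_mirna_map <- function(n_mirnas, targets_per_mirna, gene_pool,
                               seed = 1L) {
  if (n_mirnas < 0) .fail("n_mirnas must be >= 0")
  if (targets_per_mirna > length(gene_pool)) {
    .fail("gene_pool too small: ", length(gene_pool), " genes for ",
          targets_per_mirna, " targets per miRNA")
  }
  if (n_mirnas == 0) {
    return(data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  set.seed(.substream_seed(seed, 3L))
  gene_pool <- norm_symbols(gene_pool)
  maps <- lapply(seq_len(n_mirnas), function(i) {
    data.frame(mirna = sprintf("miR-%03d", i),
               gene = sort(sample(gene_pool, targets_per_mirna)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Generate a toy gene-set collection
#'
#' Builds `n_sets` random gene sets from a pool, for exercising the
#' enrichment stage; deterministic for a fixed seed.
#'
#' @param n_sets number of sets.
#' @param set_size genes per set.
#' @param gene_pool candidate symbols.
#' @param seed integer seed.
#' @return named list of character vectors (a GeneSetCollection).
#' @export
generate_gene_sets <- function(n_sets, set_size, gene_pool, seed = 1L) {
  if (set_size > length(gene_pool)) .fail("gene_pool smaller than set_size")
  set.seed(.substream_seed(seed, 4L))
  gene_pool <- norm_symbols(gene_pool)
  sets <- lapply(seq_len(n_sets), function(i) sort(sample(gene_pool, set_size)))
  names(sets) <- sprintf("pathway_%02d", seq_len(n_sets))
  sets
}
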