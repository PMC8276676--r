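# Per-gene two-group linear models with empirical-Bayes variance
# moderation, and DEG calling under dual p/fold-change threshold regimes.
#
# The moderated t follows the classical hierarchical model: per-gene
# residual variances s2_g ~ s2_tilde_g * chi^2_df / df are shrunk towards a
# prior (d0, s0^2) estimated from all genes by moment matching on log s2,
# giving t statistics with d0 + df degrees of freedom.

#' Specify a two-group contrast and its threshold regime
#'
#' Two regimes are supported. `stringent` (disease vs normal): p < 0.005
#' and |log2FC| > 1. `relaxed` (disease subtype vs subtype, or non-lesional
#' vs normal): p < 0.05 and |log2FC| > 0.5. All inequalities are strict, so
#' a gene sitting exactly on a threshold is not called.
#'
#' @param group_a,group_b phenotype labels; log2FC is `mean(a) - mean(b)`.
#' @param regime `"stringent"` or `"relaxed"`.
#' @return a `contrast_spec` list with `p_threshold` and `fc_threshold`.
#' @export
contrast_spec <- function(group_a, group_b,
                          regime = c("stringent", "relaxed")) {
  regime <- match.arg(regime)
  thr <- switch(regime,
                stringent = c(p = 0.005, fc = 1.0),
                relaxed   = c(p = 0.05,  fc = 0.5))
  structure(list(group_a = group_a, group_b = group_b, regime = regime,
                 p_threshold = unname(thr["p"]),
                 fc_threshold = unname(thr["fc"])),
            class = "contrast_spec")
}

#' Fit per-gene two-group linear models
#'
#' For each gene computes `log2fc = mean(group_a) - mean(group_b)`, the
#' pooled within-group variance `s2` with `df = n_a + n_b - 2` degrees of
#' freedom, and the variance multiplier `v = 1/n_a + 1/n_b`.
#'
#' @param em an [expression_matrix()].
#' @param contrast a [contrast_spec()].
#' @return data.frame `gene`, `log2fc`, `s2`, `df`, `v`.
#' @export
fit_gene_models <- function(em, contrast) {
  stopifnot(inherits(em, "ExpressionMatrix"),
            inherits(contrast, "contrast_spec"))
  a <- which(em$phenotype == contrast$group_a)
  b <- which(em$phenotype == contrast$group_b)
  for (g in c("group_a", "group_b")) {
    n <- length(which(em$phenotype == contrast[[g]]))
    if (n < 2) .fail("contrast group '", contrast[[g]], "' has ", n,
                     " sample(s); need >= 2")
  }
  xa <- em$values[, a, drop = FALSE]
  xb <- em$values[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  df <- na + nb - 2L
  data.frame(gene = rownames(em$values),
             log2fc = ma - mb,
             s2 = (ssa + ssb) / df,
             df = df,
             v = 1 / na + 1 / nb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on `1/x`
#' (monotone, well conditioned); returns `Inf` for `y <= 0`.
#'
#' @param y target value (vectorised).
#' @return x with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  out <- numeric(length(y))
  out[y <= 0] <- Inf
  idx <- which(y > 0)
  if (length(idx)) {
    z <- y[idx]
    x <- 0.5 + 1 / z      # starting value: trigamma(x) ~ 1/x + 1/(2x^2)
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / z) / psigamma(x, 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[idx] <- x
  }
  out
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method of moments on `z_g = log(s2_g)`: with
#' `e_g = z_g - digamma(df/2) + log(df/2)`, solves
#' `trigamma(d0/2) = max(0, var(e) - trigamma(df/2))` for the prior degrees
#' of freedom `d0` (infinite when the excess spread is zero or negative)
#' and sets `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`
#' (limit `exp(mean(e))` as `d0 -> Inf`).
#'
#' @param s2 per-gene residual variances (genes with `s2 > 0` are used;
#'   at least 10 required).
#' @param df shared residual degrees of freedom.
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
estimate_hyperparameters <- function(s2, df) {
  if (all(s2 <= 0)) .fail("degenerate variances: all s2 are zero")
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 10) .fail("need >= 10 genes with positive variance")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  excess <- stats::var(e) - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test for one or many genes
#'
#' Shrinks each variance to
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)` and tests
#' `t = log2fc / sqrt(s2_tilde * v)` against a t distribution with
#' `d0 + df` degrees of freedom (standard normal in the `d0 = Inf` limit,
#' where `s2_tilde = s0_sq`).
#'
#' @param log2fc,s2,v per-gene statistics from [fit_gene_models()]
#'   (vectorised).
#' @param df residual degrees of freedom.
#' @param hyper list with `d0`, `s0_sq` from [estimate_hyperparameters()].
#' @return data.frame `s2_tilde`, `t_mod`, `p`.
#' @export
moderated_test <- function(log2fc, s2, df, v, hyper) {
  d0 <- hyper$d0; s0 <- hyper$s0_sq
  if (is.infinite(d0)) {
    s2_tilde <- rep(s0, length(log2fc))
    t_mod <- log2fc / sqrt(s2_tilde * v)
    p <- 2 * stats::pnorm(-abs(t_mod))
  } else {
    s2_tilde <- (d0 * s0 + df * s2) / (d0 + df)
    t_mod <- log2fc / sqrt(s2_tilde * v)
    p <- 2 * stats::pt(-abs(t_mod), df = d0 + df)
  }
  data.frame(s2_tilde = s2_tilde, t_mod = t_mod, p = p)
}

#' Run the full differential-expression stage for one contrast
#'
#' Fits the per-gene models, estimates the variance prior, applies the
#' moderated t-test and flags DEGs under the contrast's threshold regime
#' (strict inequalities on both raw p and |log2FC|). A Benjamini-Hochberg
#' FDR column is included for information only; the default calls filter
#' on raw p, matching the thresholds the regimes define.
#'
#' @param em an [expression_matrix()].
#' @param contrast a [contrast_spec()].
#' @return data.frame `gene`, `log2fc`, `s2`, `s2_tilde`, `t_mod`, `p`,
#'   `bh_fdr`, `is_deg`, with the fitted hyperparameters in
#'   `attr(, "hyper")`.
#' @examples
#' d <- generate_microarray(synth_spec(300, c(lesional = 5, normal = 5),
#'                                     effect_size = 2, seed = 7))
#' res <- run_de(d$matrix, contrast_spec("lesional", "normal", "stringent"))
#' head(res[res$is_deg, ])
#' @export
run_de <- function(em, contrast) {
  fit <- fit_gene_models(em, contrast)
  hyper <- estimate_hyperparameters(fit$s2, fit$df[1])
  mt <- moderated_test(fit$log2fc, fit$s2, fit$df[1], fit$v, hyper)
  res <- data.frame(fit[c("gene", "log2fc", "s2")], mt,
                    bh_fdr = stats::p.adjust(mt$p, method = "BH"),
                    stringsAsFactors = FALSE)
  res$is_deg <- res$p < contrast$p_threshold &
    abs(res$log2fc) > contrast$fc_threshold
  attr(res, "hyper") <- hyper
  attr(res, "contrast") <- contrast
  res
}

#' Extract the DEG set called by a DE result
#'
#' @param results data.frame from [run_de()].
#' @param contrast optional [contrast_spec()]; defaults to the one stored
#'   on `results`, and re-applies its thresholds if given.
#' @return character vector of DEG symbols.
#' @export
call_degs <- function(results, contrast = NULL) {
  if (!is.null(contrast)) {
    keep <- results$p < contrast$p_threshold &
      abs(results$log2fc) > contrast$fc_threshold
  } else {
    keep <- results$is_deg
  }
  norm_symbols(results$gene[keep])
}

#' Volcano table for plotting
#'
#' @param results data.frame from [run_de()].
#' @return data.frame `gene`, `log2fc`, `neg_log10_p`, `is_deg`.
#' @export
volcano_table <- function(results) {
  data.frame(gene = results$gene, log2fc = results$log2fc,
             neg_log10_p = -log10(results$p), is_deg = results$is_deg,
             stringsAsFactors = FALSE)
}
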