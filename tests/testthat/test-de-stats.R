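test_that("per-gene fits match hand-computed pooled statistics", {
  em <- toy_matrix(list(FLAT = c(1, 1, 1, 1), SHIFT = c(3, 5, 1, 1)),
                   c("a", "a", "b", "b"))
  fit <- fit_gene_models(em, contrast_spec("a", "b", "stringent"))
  flat <- fit[fit$gene == "FLAT", ]
  expect_equal(flat$log2fc, 0)
  expect_equal(flat$s2, 0)
  shift <- fit[fit$gene == "SHIFT", ]
  expect_equal(shift$log2fc, 3)
  expect_equal(shift$s2, 1)   # (2 + 0) / 2
  expect_equal(shift$df, 2)
  expect_equal(shift$v, 1)
})

test_that("reversing the contrast negates log2fc and preserves s2 and p", {
  d <- generate_microarray(synth_spec(200, c(a = 4, b = 5),
                                      effect_size = 1.5, seed = 8))
  fwd <- run_de(d$matrix, contrast_spec("a", "b", "stringent"))
  rev <- run_de(d$matrix, contrast_spec("b", "a", "stringent"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$s2, fwd$s2)
  expect_equal(rev$p, fwd$p)
})

test_that("contrast errors name the offending group", {
  em <- toy_matrix(list(G1 = c(1, 2, 3)), c("a", "a", "b"))
  expect_error(fit_gene_models(em, contrast_spec("a", "b", "stringent")),
               "'b'")
  expect_error(fit_gene_models(em, contrast_spec("a", "c", "stringent")),
               "'c'")
})

test_that("trigamma inverse is a right-inverse and handles fixed points", {
  for (df in c(2, 4, 10)) {
    expect_equal(trigamma_inverse(trigamma(df / 2)), df / 2,
                 tolerance = 1e-8)
  }
  expect_identical(trigamma_inverse(0), Inf)
  expect_identical(trigamma_inverse(-1), Inf)
})

test_that("identical variances give an infinite prior df", {
  h <- estimate_hyperparameters(rep(2, 50), df = 4)
  expect_identical(h$d0, Inf)
  mt <- moderated_test(1, 2, 4, 0.5, h)
  expect_equal(mt$s2_tilde, h$s0_sq)
  expect_error(estimate_hyperparameters(rep(0, 50), 4), "degenerate")
})

test_that("hyperparameters are recovered from a scaled-chi-square mixture", {
  # true d0 = 4, s0^2 = 1, df = 4, 5000 genes; a 100-replicate Monte-Carlo
  # run of this recovery gives d0 in [3.77, 4.54] and s0^2 in [0.96, 1.04],
  # well inside the asserted bands
  set.seed(14)
  s2g <- 4 / stats::rchisq(5000, df = 4)
  s2 <- s2g * stats::rchisq(5000, df = 4) / 4
  h <- estimate_hyperparameters(s2, df = 4)
  expect_gt(h$d0, 2.8); expect_lt(h$d0, 5.6)
  expect_gt(h$s0_sq, 0.8); expect_lt(h$s0_sq, 1.25)
})

test_that("moderated test matches hand arithmetic and an independent t CDF", {
  mt <- moderated_test(log2fc = 1, s2 = 2, df = 4, v = 0.5,
                       hyper = list(d0 = 6, s0_sq = 1))
  expect_equal(mt$s2_tilde, 1.4)          # (6*1 + 4*2) / 10
  expect_equal(mt$t_mod, 1 / sqrt(0.7))
  # independent check of the two-sided tail via numerical integration of
  # the t_10 density
  dens <- function(x) dt(x, df = 10)
  p_num <- 2 * integrate(dens, abs(mt$t_mod), Inf)$value
  expect_equal(mt$p, p_num, tolerance = 1e-6)
  expect_equal(moderated_test(0, 2, 4, 0.5, list(d0 = 6, s0_sq = 1))$p, 1)
})

test_that("moderation vanishes at d0 = 0 and dominates at d0 = Inf", {
  s2 <- c(0.5, 2, 4); lfc <- c(1, -2, 0.3); v <- 0.5; df <- 4
  plain <- moderated_test(lfc, s2, df, v, list(d0 = 0, s0_sq = 1))
  expect_equal(plain$s2_tilde, s2)
  expect_equal(plain$t_mod, lfc / sqrt(s2 * v))
  inf <- moderated_test(lfc, s2, df, v, list(d0 = Inf, s0_sq = 1.3))
  expect_equal(inf$s2_tilde, rep(1.3, 3))
  expect_equal(inf$t_mod, lfc / sqrt(1.3 * v))
})

test_that("s2_tilde always lies between s0_sq and s2", {
  s2 <- exp(stats::rnorm(100))
  for (d0 in c(0.5, 2, 10)) {
    st <- moderated_test(1, s2, 4, 0.5, list(d0 = d0, s0_sq = 1))$s2_tilde
    expect_true(all(st >= pmin(s2, 1) - 1e-12 & st <= pmax(s2, 1) + 1e-12))
  }
})

test_that("DEG calling uses strict thresholds in both regimes", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(1.0, 1.2, -0.6, -0.5),
                    p = c(0.004, 0.004, 0.04, 0.04))
  expect_identical(call_degs(res, contrast_spec("x", "y", "stringent")), "B")
  expect_identical(call_degs(res, contrast_spec("x", "y", "relaxed")),
                   c("A", "B", "C"))
  # -0.5 sits exactly on the relaxed fold-change bound: not a call
  expect_false("D" %in% call_degs(res, contrast_spec("x", "y", "relaxed")))
  # exactly at the p threshold is not a call either
  res2 <- data.frame(gene = "E", log2fc = 2, p = 0.005)
  expect_length(call_degs(res2, contrast_spec("x", "y", "stringent")), 0)
})

test_that("run_de agrees with limma on a finite-d0 dataset", {
  skip_if_not_installed("limma")
  set.seed(21)
  n <- 600
  s2g <- 4 / stats::rchisq(n, 4)
  vals <- matrix(stats::rnorm(n * 6, 7, sqrt(rep(s2g, 6))), n, 6,
                 dimnames = list(sprintf("G%04d", 1:n), paste0("s", 1:6)))
  em <- expression_matrix(vals, stats::setNames(rep(c("a", "b"), each = 3),
                                                colnames(vals)))
  res <- run_de(em, contrast_spec("a", "b", "stringent"))
  design <- stats::model.matrix(~ 0 + factor(em$phenotype, c("a", "b")))
  colnames(design) <- c("a", "b")
  fit <- limma::lmFit(em$values, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(a - b,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  h <- attr(res, "hyper")
  expect_equal(h$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(h$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("null type-I rate of the stringent p threshold is calibrated", {
  # raw two-sided p < 0.005 on null data; 99% binomial band for 4000 genes
  d <- generate_microarray(synth_spec(4000, c(lesional = 5, normal = 5),
                                      deg_fraction = 0, effect_size = 0,
                                      seed = 5))
  res <- run_de(d$matrix, contrast_spec("lesional", "normal", "stringent"))
  rate <- mean(res$p < 0.005)
  band <- stats::qbinom(c(0.005, 0.995), 4000, 0.005) / 4000
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("planted DEGs at effect 2 are recovered under the stringent regime", {
  d <- generate_microarray(synth_spec(2000, c(lesional = 5, normal = 5),
                                      deg_fraction = 0.05, effect_size = 2,
                                      sigma = 0.5, seed = 3))
  res <- run_de(d$matrix, contrast_spec("lesional", "normal", "stringent"))
  planted <- d$truth$gene[d$truth$is_deg]
  expect_gte(mean(planted %in% call_degs(res)), 0.9)
})

test_that("volcano table mirrors the DE result", {
  d <- generate_microarray(synth_spec(50, c(a = 3, b = 3), seed = 2))
  res <- run_de(d$matrix, contrast_spec("a", "b", "relaxed"))
  v <- volcano_table(res)
  expect_equal(v$neg_log10_p, -log10(res$p))
  expect_equal(nrow(v), nrow(res))
})
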