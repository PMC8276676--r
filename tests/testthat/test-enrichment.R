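test_that("hypergeometric p matches exhaustive enumeration for all N <= 12", {
  for (N in c(5, 8, 12)) {
    universe <- sprintf("g%02d", seq_len(N))
    for (K in c(2, floor(N / 2), N - 1)) {
      for (n in c(2, floor(N / 2))) {
        degs <- universe[seq_len(n)]
        set <- universe[seq_len(K)]
        res <- enrich(degs, universe, list(S = set))
        x <- length(intersect(set, degs))
        expect_equal(res$p, enum_hyper_p(N, K, n, x), tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("boundary cases: zero overlap and saturated draws give p = 1", {
  universe <- LETTERS[1:10]
  res0 <- enrich(c("A", "B", "C"), universe, list(S = c("H", "I", "J")))
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p, 1)
  # degs = universe: overlap is forced, so the upper tail is certain
  resU <- enrich(universe, universe, list(S = c("A", "B", "C", "D")))
  expect_equal(resU$overlap, 4)
  expect_equal(resU$p, 1)
})

test_that("worked example: N=10, K=4, n=3, x=3", {
  universe <- LETTERS[1:10]
  res <- enrich(LETTERS[1:3], universe, list(S = LETTERS[1:4]))
  expect_equal(res$p, 4 / 120)
  expect_true(res$significant)
})

test_that("p is monotone non-increasing in the overlap", {
  # same N, K, n; vary x by choosing DEG sets with growing overlap
  universe <- sprintf("u%02d", 1:12)
  set <- universe[1:5]
  ps <- vapply(0:4, function(x) {
    degs <- c(head(set, x), setdiff(universe, set)[seq_len(4 - x)])
    enrich(degs, universe, list(S = set))$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("DEGs outside the universe are a validation error", {
  expect_error(enrich(c("A", "ZZZ"), LETTERS[1:5], list(S = "A")), "ZZZ")
  expect_error(enrich("A", LETTERS[1:5], list()), "empty")
})

test_that("results are sorted by p with label tie-breaks and carry BH FDR", {
  universe <- LETTERS[1:12]
  coll <- list(zeta = LETTERS[1:3], alpha = LETTERS[1:3],
               weak = LETTERS[10:12])
  res <- enrich(LETTERS[1:3], universe, coll)
  expect_identical(res$pathway[1:2], c("alpha", "zeta"))
  expect_true(all(diff(res$p) >= 0))
  expect_equal(res$bh_fdr, stats::p.adjust(res$p, "BH"))
})

test_that("random DEG draws are significant at about the nominal rate", {
  # 400 uniform draws; per-pathway significant rate <= 0.05 within a 99%
  # binomial band
  set.seed(77)
  universe <- sprintf("g%03d", 1:60)
  set <- universe[1:12]
  hits <- vapply(1:400, function(i) {
    degs <- sample(universe, 8)
    enrich(degs, universe, list(S = set))$significant
  }, logical(1))
  upper <- stats::qbinom(0.995, 400, 0.05) / 400
  expect_lte(mean(hits), upper)
})

test_that("GMT round-trip preserves sets and normalises symbols", {
  sets <- list(A = c("TNF", "IL1B"), B = c("s100a8", "LCN2", "MMP9"))
  attr(sets$A, "description") <- "first"
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), c("A", "B"))
  expect_identical(as.character(back$B), c("LCN2", "MMP9", "S100A8"))
  expect_identical(attr(back$A, "description"), "first")
})

test_that("the shipped collection contains the IL-17 signalling set", {
  gmt <- read_gmt(system.file("extdata", "il17_sets.gmt",
                              package = "il17path"))
  expect_true("IL-17 signaling pathway" %in% names(gmt))
  il17 <- gmt[["IL-17 signaling pathway"]]
  expect_true(all(c("S100A8", "MAPK14", "CXCL8", "TNF", "FOSL1") %in% il17))
})

test_that("common significant pathways intersect across datasets", {
  r1 <- data.frame(pathway = c("IL-17 signaling pathway", "Ribosome"),
                   significant = c(TRUE, TRUE))
  r2 <- data.frame(pathway = c("IL-17 signaling pathway", "Cell cycle"),
                   significant = c(TRUE, TRUE))
  common <- common_significant_pathways(list(a = r1, b = r2))
  expect_identical(as.character(common), "IL-17 signaling pathway")
  r3 <- data.frame(pathway = "Ribosome", significant = FALSE)
  expect_length(common_significant_pathways(list(a = r1, b = r3)), 0)
  expect_identical(
    as.character(common_significant_pathways(list(a = r1, b = r1))),
    sort(r1$pathway))
  expect_error(common_significant_pathways(list(a = r1)), ">= 2")
})
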