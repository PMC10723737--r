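test_that("lens correlation matches the direct Pearson formula", {
  set.seed(61)
  x <- matrix(runif(6 * 5, 0, 8), 6,
    dimnames = list(paste0("og", 1:6), paste0("s", 1:5)))
  tpm <- 2^x - 1
  f <- setNames(runif(5), colnames(tpm))
  tbl <- lensCorrelation(tpm, f)
  for (i in 1:6) {
    expect_equal(tbl$r[i], bfPearson(x[i, ], f), tolerance = 1e-12)
  }
  # a row equal to the lens values correlates perfectly
  x2 <- rbind(x, ogf = f)
  tbl2 <- lensCorrelation(2^x2 - 1, f)
  expect_equal(tbl2$r[tbl2$orthogroup == "ogf"], 1, tolerance = 1e-12)
  # constant rows are flagged with r = 0
  x3 <- rbind(x, ogc = rep(2, 5))
  tbl3 <- lensCorrelation(2^x3 - 1, f)
  expect_equal(tbl3$r[tbl3$orthogroup == "ogc"], 0)
  expect_true(tbl3$degenerate[tbl3$orthogroup == "ogc"])
  expect_error(lensCorrelation(tpm[, 1:2], f[1:2]), "3 shared")
})

test_that("tail selection slices the ranked table deterministically", {
  set.seed(62)
  tbl <- data.frame(orthogroup = sprintf("OG%03d", 1:200),
    r = runif(200, -1, 1), degenerate = FALSE)
  tails <- selectExtremes(tbl, 0.025)
  expect_length(tails$positive, 5)
  expect_length(tails$negative, 5)
  # sorting oracle
  srt <- tbl[order(-tbl$r, tbl$orthogroup), ]
  expect_identical(tails$positive, srt$orthogroup[1:5])
  expect_identical(tails$negative, rev(srt$orthogroup)[1:5])
  # all-equal correlations: deterministic id-ordered selection
  tbl2 <- data.frame(orthogroup = sprintf("OG%03d", 1:100), r = 0.5,
    degenerate = FALSE)
  t2 <- selectExtremes(tbl2, 0.05)
  expect_identical(t2$positive, sprintf("OG%03d", 1:5))
  expect_identical(t2$negative, sprintf("OG%03d", 1:5))
  # degenerate rows never enter the tails
  tbl3 <- tbl; tbl3$degenerate[tbl3$orthogroup %in% tails$positive] <- TRUE
  t3 <- selectExtremes(tbl3, 0.025)
  expect_length(intersect(t3$positive, tails$positive), 0)
  expect_error(selectExtremes(tbl, 0.001), "0")
  expect_error(selectExtremes(tbl, 0.6), "tailFrac")
})

test_that("binomial enrichment p-values are exact", {
  universe <- paste0("g", 1:100)
  sel <- paste0("g", 1:10)
  # reference = half the universe, selection fully inside it:
  # P(X >= 10 | n = 10, p0 = 0.5) = 2^-10
  ref <- paste0("g", 1:50)
  res <- binomialEnrichment(sel, ref, universe, "greater")
  expect_equal(res$pValue, 2^-10, tolerance = 1e-15)
  expect_equal(res$k, 10); expect_equal(res$p0, 0.5)
  # zero overlap in the greater direction is certain
  res0 <- binomialEnrichment(paste0("g", 51:60), paste0("g", 1:10),
    universe, "greater")
  expect_equal(res0$pValue, 1)
  # matches closed-tail summation via pbinom across sizes up to 1,000
  set.seed(63)
  for (i in 1:20) {
    N <- sample(50:1000, 1)
    uni <- paste0("u", seq_len(N))
    ref <- sample(uni, sample(5:(N / 2), 1))
    sel <- sample(uni, sample(5:min(N, 1000), 1))
    for (dir in c("greater", "less")) {
      r <- binomialEnrichment(sel, ref, uni, dir)
      oracle <- if (dir == "greater")
        pbinom(r$k - 1, r$n, r$p0, lower.tail = FALSE)
        else pbinom(r$k, r$n, r$p0)
      expect_equal(r$pValue, oracle, tolerance = 1e-12)
    }
  }
  expect_error(binomialEnrichment(sel, ref, character(0)), "empty universe")
  expect_error(binomialEnrichment(c(universe, "gX"), ref, universe),
    "subset")
})

test_that("hypergeometric term enrichment matches combinatorics and BH", {
  universe <- paste0("g", 1:10)
  sel <- paste0("g", 1:5)
  terms <- list(hit = paste0("g", 1:5), miss = paste0("g", 6:10))
  res <- flatSetEnrichment(sel, terms, universe)
  # overlap 5 of 5 from a 5-member term in a 10-member universe:
  # C(5,5) C(5,0) / C(10,5) = 1/252
  expect_equal(res$pValue[res$term == "hit"], 1 / 252, tolerance = 1e-15)
  # disjoint term: upper tail at k = 0 is 1
  expect_equal(res$pValue[res$term == "miss"], 1)
  # phyper cross-check on random instances
  set.seed(64)
  for (i in 1:15) {
    N <- sample(30:400, 1)
    uni <- paste0("u", seq_len(N))
    sel <- sample(uni, sample(5:20, 1))
    terms <- setNames(lapply(1:4, function(j)
      sample(uni, sample(3:(N / 2), 1))), paste0("t", 1:4))
    res <- flatSetEnrichment(sel, terms, uni)
    for (j in seq_len(nrow(res))) {
      expect_equal(res$pValue[j],
        phyper(res$k[j] - 1, res$K[j], N - res$K[j], res$n[j],
          lower.tail = FALSE), tolerance = 1e-12)
    }
    # BH q-values are monotone in ranked p order
    expect_true(all(diff(res$qValue[order(res$pValue)]) >= -1e-15))
    expect_equal(res$qValue, p.adjust(res$pValue, "BH"))
  }
  expect_equal(nrow(flatSetEnrichment(sel, list(), uni)), 0)
})

test_that("adjusted R-squared follows the closed form", {
  expect_equal(adjustedR2(1, 22, 1), 1)
  expect_equal(adjustedR2(0.5, 22, 1), 0.475)
  expect_equal(adjustedR2(0, 22, 1), -0.05)
  expect_error(adjustedR2(0.5, 3, 2), "exceed")
  expect_error(adjustedR2(1.5, 22, 1), "lie in")
  # agrees with the adjustment reported by lm() on a random fit
  set.seed(65)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  sm <- summary(lm(y ~ x, d))
  expect_equal(adjustedR2(sm$r.squared, 30, 1), sm$adj.r.squared,
    tolerance = 1e-12)
})

test_that("GMT files round-trip", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = "g9")
  p <- tempfile(fileext = ".gmt")
  writeGmt(sets, p, descriptions = c("first", "second"))
  expect_identical(readGmt(p), sets)
})
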