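test_that("domain burden tables combine neutral and observed views", {
  gm <- makeToyGene(L = 60, seed = 31)
  dm <- DomainMap("toygene", data.frame(domain = c("N1", "C1"),
                                        start = c(1, 31), end = c(20, 50)))
  tab <- enumerateEvents(gm, seq_len(60), substitutionWeights("uniform"))
  spec <- syntheticSpec(L = 60, N = 50, seed = 32, nonsenseRate = 0)
  coh <- cohortFromMafDf(gm, makeCohort(spec, gm))
  s <- summarizeCohort(coh, dm)
  dt <- buildDomainTable(tab, s, dm)

  expect_equal(dt$domain, c("N1", "C1", "Other"))
  expect_equal(sum(dt$neutral_frac), 1)
  expect_equal(sum(dt$observed_frac), 1)
  expect_equal(sum(dt$observed_count), s@nMissense)
  nz <- dt$neutral_frac > 0 & dt$observed_count > 0
  expect_equal(dt$enrichment[nz],
               dt$observed_frac[nz] / dt$neutral_frac[nz])
  ## neutral mean decomposes the global expectation
  ns <- neutralSummary(tab)
  expect_equal(sum(dt$neutral_frac * dt$neutral_mean_score), ns$meanScore)
})

test_that("zero-observed domains report enrichment 0 and an empty-mean flag", {
  gm <- GeneModel(paste0("ATG", strrep("CGT", 9)), "g")  # 10 codons
  dm <- DomainMap("g", data.frame(domain = c("A1", "B1"),
                                  start = c(1, 6), end = c(5, 10)))
  tab <- enumerateEvents(gm, 1:10, substitutionWeights("uniform"))
  v <- parseHgvsp(c("p.R2H", "p.R3K"))  # both in A1
  s <- summarizeCohort(observedCohort(gm, v), dm)
  dt <- buildDomainTable(tab, s, dm)
  b <- dt[dt$domain == "B1", ]
  expect_equal(b$observed_count, 0L)
  expect_equal(b$enrichment, 0)
  expect_equal(b$observed_mean_score, 0)
  expect_true(b$observed_empty)
  expect_false(any(dt$flagged))
})

test_that("goodness of fit is exact on hand-computed tables", {
  perfect <- goodnessOfFit(c(30, 70), c(0.3, 0.7))
  expect_equal(perfect@chi2, 0)
  expect_equal(perfect@G, 0)
  expect_equal(perfect@chi2P, 1)
  expect_equal(perfect@GP, 1)

  g <- goodnessOfFit(c(8, 2), c(0.5, 0.5))
  expect_equal(g@chi2, 3.6)
  expect_equal(g@G, 2 * (8 * log(1.6) + 2 * log(0.4)))
  expect_equal(g@G, 3.85490, tolerance = 1e-5)
  expect_equal(g@df, 1L)
  expect_equal(g@chi2P, stats::pchisq(3.6, 1, lower.tail = FALSE))

  ## zero observed count: G term contributes 0, chi-square contributes E_d
  z <- goodnessOfFit(c(10, 0), c(0.5, 0.5))
  expect_equal(z@chi2, (10 - 5)^2 / 5 + 5)
  expect_equal(z@G, 2 * 10 * log(2))
})

test_that("gof preconditions are enforced and probabilities renormalized", {
  expect_error(goodnessOfFit(c(5, 5), c(0.5, 0.5), N = 11), "sum to N")
  expect_error(goodnessOfFit(c(5, 5), c(1, 0)), "merge categories")
  expect_error(goodnessOfFit(integer(2), c(0.5, 0.5)), "N must be positive")
  ## unnormalized neutral fractions (as printed tables have) are renormalized
  expect_message(r <- goodnessOfFit(c(8, 2), c(0.2, 0.2)), "renormalizing")
  expect_equal(r@chi2, 3.6)
  expect_equal(r@expected, c(5, 5))
})

test_that("chi-square and G agree asymptotically on large expected counts", {
  set.seed(14)
  probs <- c(0.3, 0.3, 0.2, 0.2)
  for (i in 1:5) {
    O <- as.integer(stats::rmultinom(1, 5000, prob = c(0.32, 0.28, 0.21, 0.19)))
    g <- suppressMessages(goodnessOfFit(O, probs))
    expect_true(all(g@expected >= 20))
    expect_lt(abs(g@chi2 - g@G) / max(g@chi2, g@G), 0.05)
  }
})

test_that("merging categories never increases G", {
  set.seed(15)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    probs <- as.numeric(stats::rgamma(k, 2)); probs <- probs / sum(probs)
    O <- as.integer(stats::rmultinom(1, 200, prob = probs))
    if (any(O == 0)) O[O == 0] <- 1L  # keep N consistent afterwards
    g <- suppressMessages(goodnessOfFit(O, probs, N = sum(O)))
    mergedO <- c(O[1] + O[2], O[-(1:2)])
    mergedP <- c(probs[1] + probs[2], probs[-(1:2)])
    gm <- suppressMessages(goodnessOfFit(mergedO, mergedP, N = sum(O)))
    expect_lte(gm@G, g@G + 1e-9)
  }
})

test_that("enrichment ratios divide observed by neutral fractions", {
  expect_equal(enrichmentRatio(0.3824, 0.1666), 0.3824 / 0.1666)
  expect_equal(enrichmentRatio(0.5, 0), NA_real_)
  expect_equal(enrichmentRatio(c(0.2, 0), c(0.1, 0.4)), c(2, 0))
})
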