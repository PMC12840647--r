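test_that("single-codon event sets match hand enumeration", {
  uni <- substitutionWeights("uniform")
  gm <- GeneModel("ATGCGT", "g")  # codon 2 is CGT (Arg)
  tab <- enumerateEvents(gm, 2L, uni)
  ev <- events(tab)
  expect_equal(nrow(ev), 6L)  # 9 neighbours - 3 synonymous
  expect_setequal(ev$mut_aa, c("S", "G", "C", "H", "P", "L"))
  expect_equal(ev$prob, rep(1 / 6, 6))

  gm2 <- GeneModel("ATGTGG", "g2")  # codon 2 is TGG (Trp)
  tab2 <- enumerateEvents(gm2, 2L, uni)
  ev2 <- events(tab2)
  expect_equal(nrow(ev2), 7L)  # TAG and TGA dropped as stop gains
  expect_false("*" %in% ev2$mut_aa)
  expect_equal(sum(ev2$prob), 1)
})

test_that("expected severity matches the hand-computed CGT average", {
  ## CGT missense neighbours score (S,G,C,H,P,L vs R): -1,-2,-3,0,-2,-2
  gm <- GeneModel("ATGCGT", "g")
  tab <- enumerateEvents(gm, 2L, substitutionWeights("uniform"))
  ns <- neutralSummary(tab)
  expect_equal(ns$meanScore, -10 / 6)
  expect_equal(ns$radicalFraction, 1)  # all six scores are <= 0
})

test_that("degenerate event distributions summarize correctly", {
  one <- manualEventTable(scores = -1, probs = 1)
  expect_equal(neutralSummary(one), list(meanScore = -1, radicalFraction = 1))
  two <- manualEventTable(scores = c(2, -2), probs = c(0.5, 0.5))
  expect_equal(neutralSummary(two), list(meanScore = 0, radicalFraction = 0.5))
})

test_that("zero-weight events are retained with probability zero", {
  nm <- substitutionPairNames()
  vals <- stats::setNames(rep(1, 12), nm)
  vals["C>A"] <- 0  # kills the CGT -> AGT (R -> S) event
  w <- substitutionWeights(values = vals)
  tab <- enumerateEvents(GeneModel("ATGCGT", "g"), 2L, w)
  ev <- events(tab)
  expect_equal(nrow(ev), 6L)  # event count unchanged
  dead <- ev[ev$from_base == "C" & ev$to_base == "A", ]
  expect_equal(dead$prob, 0)
  expect_equal(sum(ev$prob), 1)
})

test_that("degenerate inputs are rejected", {
  gm <- GeneModel("ATGCGT", "g")
  uni <- substitutionWeights("uniform")
  expect_error(enumerateEvents(gm, integer(0), uni), "non-empty")
  expect_error(enumerateEvents(gm, 5L, uni), "1..2", fixed = TRUE)
  ## all weight on pairs the CGT neighbourhood never uses -> total weight 0
  vals <- stats::setNames(rep(0, 12), substitutionPairNames())
  vals["A>C"] <- 1
  expect_error(enumerateEvents(gm, 2L, substitutionWeights(values = vals)),
               "total raw weight")
})

test_that("event probabilities are invariant to rescaling the weights", {
  gm <- makeToyGene(L = 25, seed = 7)
  w <- randomWeights(11)
  scaled <- substitutionWeights(values = w@w * 57.3)
  t1 <- enumerateEvents(gm, seq_len(25), w)
  t2 <- enumerateEvents(gm, seq_len(25), scaled)
  expect_equal(eventProbs(t1), eventProbs(t2))
})

test_that("enumeration agrees with the brute-force oracle on random toy genes", {
  for (seed in 1:10) {
    L <- sample(2:50, 1)
    gm <- makeToyGene(L = L, seed = seed)
    positions <- sort(sample(seq_len(L), sample(seq_len(L), 1)))
    w <- randomWeights(seed + 100)
    got <- sortEvents(events(enumerateEvents(gm, positions, w)))
    want <- sortEvents(bruteForceEvents(gm, positions, w))
    attr(want, "neighbour_classes") <- NULL
    expect_equal(got, want)
  }
})

test_that("every codon has exactly nine single-nucleotide neighbours", {
  gm <- makeToyGene(L = 40, seed = 3)
  oracle <- bruteForceEvents(gm, seq_len(40), substitutionWeights("uniform"))
  classes <- attr(oracle, "neighbour_classes")
  perCodon <- table(classes$codon_index)
  expect_true(all(perCodon == 9L))
  ## and the three classes partition the nine
  split <- table(classes$codon_index, classes$class)
  expect_true(all(rowSums(split) == 9L))
})
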