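test_that("a single-event table gives degenerate replicates", {
  tab <- manualEventTable(scores = -1, probs = 1)
  reps <- simulateReplicates(tab, N = 5, M = 10, seed = 1)
  expect_true(all(meanScores(reps) == -1))
  expect_true(all(radicalFractions(reps) == 1))
  tst <- pValues(reps, muObs = -1, rObs = 1)
  expect_equal(tst@pMean, 1)       # all replicates tied with the observed
  expect_equal(tst@pMeanOpposite, 1)
  expect_equal(tst@pRad, 1)
})

test_that("replicates are reproducible under a fixed seed", {
  gm <- makeToyGene(L = 30, seed = 2)
  tab <- enumerateEvents(gm, seq_len(30), substitutionWeights("titv"))
  r1 <- simulateReplicates(tab, N = 20, M = 50, seed = 99)
  r2 <- simulateReplicates(tab, N = 20, M = 50, seed = 99)
  expect_identical(meanScores(r1), meanScores(r2))
  expect_identical(radicalFractions(r1), radicalFractions(r2))
  r3 <- simulateReplicates(tab, N = 20, M = 50, seed = 100)
  expect_false(identical(meanScores(r1), meanScores(r3)))
})

test_that("replicate radical fractions match the binomial closed form", {
  ## two equiprobable events with scores {1, -1}: r_s ~ Binomial(N, 1/2)/N
  tab <- manualEventTable(scores = c(1, -1), probs = c(0.5, 0.5))
  N <- 100; M <- 2000
  reps <- simulateReplicates(tab, N = N, M = M, seed = 7)
  se <- sqrt(0.5 * 0.5 / N) / sqrt(M)   # MC SE of the mean of r_s
  expect_lt(abs(mean(radicalFractions(reps)) - 0.5), 3 * se)
  ## replicate means live on the score lattice bounds
  expect_true(all(meanScores(reps) >= -1 & meanScores(reps) <= 1))
})

test_that("one-sided p-values follow the indicator-sum definitions", {
  reps <- new("ReplicateSet", M = 4L, N = 10L, seed = 1L,
              meanScores = c(-1, 0, 0.5, 1),
              radicalFractions = c(0.2, 0.4, 0.6, 0.8))
  tst <- pValues(reps, muObs = -2, rObs = 0.5)
  expect_equal(tst@pMean, 0)           # observed below every replicate mean
  expect_equal(tst@pMeanOpposite, 1)
  expect_equal(tst@pRad, 2 / 4)
  expect_equal(tst@pRadOpposite, 2 / 4)

  tst0 <- pValues(reps, muObs = 0, rObs = 0)
  expect_equal(tst0@pRad, 1)           # every replicate fraction >= 0
  expect_equal(tst0@pMean, 2 / 4)      # non-strict inequality counts the tie

  tstAdd <- pValues(reps, muObs = -2, rObs = 0.5, correction = "add-one")
  expect_equal(tstAdd@pMean, 1 / 5)    # never exactly zero
  expect_equal(tstAdd@pRad, 3 / 5)
})

test_that("p-values are invariant to replicate order and carry MC errors", {
  gm <- makeToyGene(L = 20, seed = 4)
  tab <- enumerateEvents(gm, seq_len(20), substitutionWeights("uniform"))
  reps <- simulateReplicates(tab, N = 30, M = 200, seed = 5)
  perm <- sample(200)
  shuffled <- new("ReplicateSet", M = 200L, N = 30L, seed = 5L,
                  meanScores = meanScores(reps)[perm],
                  radicalFractions = radicalFractions(reps)[perm])
  t1 <- pValues(reps, -0.5, 0.7)
  t2 <- pValues(shuffled, -0.5, 0.7)
  expect_equal(t1@pMean, t2@pMean)
  expect_equal(t1@pRad, t2@pRad)
  expect_equal(unname(t1@mcSe["p_mean"]),
               sqrt(t1@pMean * (1 - t1@pMean) / 200))
})

test_that("replicate means converge to the analytic neutral expectation", {
  gm <- makeToyGene(L = 40, seed = 8)
  tab <- enumerateEvents(gm, seq_len(40), substitutionWeights("titv"))
  ns <- neutralSummary(tab)
  N <- 50; M <- 4000
  reps <- simulateReplicates(tab, N = N, M = M, seed = 21)
  sdEvent <- sqrt(sum(eventProbs(tab) * (eventScores(tab) - ns$meanScore)^2))
  se <- sdEvent / sqrt(N) / sqrt(M)
  expect_lt(abs(mean(meanScores(reps)) - ns$meanScore), 3 * se)
})

test_that("convergence diagnostics report the grid and flag jumps", {
  one <- manualEventTable(scores = -1, probs = 1)
  cc <- convergenceCheck(one, N = 10, seed = 1, mGrid = c(100L, 200L, 400L),
                         muObs = -1, rObs = 1)
  expect_equal(cc$p_mean, rep(1, 3))   # deterministic table: identical grid
  expect_false(any(cc$flag_mean))
  expect_false(any(cc$flag_rad))

  single <- convergenceCheck(one, N = 10, seed = 1, mGrid = 100L,
                             muObs = -1, rObs = 1)
  expect_equal(nrow(single), 1L)
  expect_false(single$flag_mean)

  ## null self-test: observed value drawn from the table itself stabilizes
  gm <- makeToyGene(L = 30, seed = 12)
  tab <- enumerateEvents(gm, seq_len(30), substitutionWeights("uniform"))
  ns <- neutralSummary(tab)
  cc2 <- convergenceCheck(tab, N = 50, seed = 2,
                          mGrid = c(500L, 1000L, 2000L, 4000L, 7600L),
                          muObs = ns$meanScore, rObs = ns$radicalFraction)
  expect_equal(nrow(cc2), 5L)
  expect_false(any(cc2$flag_mean))
  expect_false(any(cc2$flag_rad))
  expect_error(convergenceCheck(tab, 10, 1, mGrid = c(200L, 100L)),
               "increasing")
})
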