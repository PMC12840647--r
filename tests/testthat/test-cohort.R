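mafRows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(case_id = r[1], gene = r[2], protein_change = r[3],
               variant_class = r[4], stringsAsFactors = FALSE)))
}

test_that("MAF-lite reading filters by gene and variant class", {
  path <- writeMafLite(mafRows(
    c("c1", "TP53", "p.R2H", "missense"),
    c("c2", "TP53", "p.R2R", "synonymous"),
    c("c3", "TP53", "p.Q3*", "nonsense"),
    c("c4", "OTHER", "p.R2H", "missense")))
  v <- readMafLite(path, "TP53")
  expect_equal(nrow(v), 2L)
  expect_equal(v$kind, c("missense", "nonsense"))
  expect_equal(v$case_id, c("c1", "c3"))
  expect_equal(attr(v, "n_skipped"), 0L)
})

test_that("duplicate (case, change) rows collapse unless per-biospecimen", {
  path <- writeMafLite(mafRows(
    c("c1", "g", "p.R2H", "missense"),
    c("c1", "g", "p.R2H", "missense"),
    c("c2", "g", "p.R2H", "missense")))
  expect_equal(nrow(readMafLite(path, "g")), 2L)  # once per case
  expect_equal(nrow(readMafLite(path, "g", perBiospecimen = TRUE)), 3L)
})

test_that("unparseable rows are skipped with a warning and counted", {
  path <- writeMafLite(mafRows(
    c("c1", "g", "p.R2H", "missense"),
    c("c2", "g", "garbage", "missense")))
  expect_warning(v <- readMafLite(path, "g"), "skipped 1")
  expect_equal(nrow(v), 1L)
  expect_equal(attr(v, "n_skipped"), 1L)
})

test_that("missing columns and empty cohorts behave as contracted", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("case_id\tgene\tprotein_change", "c1\tg\tp.R2H"), bad)
  expect_error(readMafLite(bad, "g"), "missing column")

  path <- writeMafLite(mafRows(c("c1", "other", "p.R2H", "missense")))
  v <- readMafLite(path, "g")
  expect_equal(nrow(v), 0L)
})

test_that("GDC MAF column names are adapted onto the MAF-lite schema", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(Tumor_Sample_Barcode = c("s1", "s2"),
                   Hugo_Symbol = "TP53",
                   HGVSp_Short = c("p.R2H", "p.Q3*"),
                   Variant_Classification = c("Missense_Mutation",
                                              "Nonsense_Mutation"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- readMafLite(path, "TP53")
  expect_equal(v$kind, c("missense", "nonsense"))
  expect_equal(v$case_id, c("s1", "s2"))
})

test_that("cohort summaries follow the mean/radical definitions", {
  ## protein M R W: R2K scores 2, R2S scores -1
  gm <- GeneModel("ATGCGTTGG", "g")
  v <- parseHgvsp(c("p.R2K", "p.R2S"))
  v$case_id <- c("c1", "c2")
  coh <- observedCohort(gm, v)
  s <- summarizeCohort(coh)
  expect_equal(s@nMissense, 2L)
  expect_equal(s@meanScore, 0.5)
  expect_equal(s@radicalFraction, 0.5)

  vOne <- parseHgvsp("p.W3G")  # B(W,G) = -2... single radical variant
  coh1 <- observedCohort(gm, vOne)
  s1 <- summarizeCohort(coh1)
  expect_equal(s1@meanScore, blosumScore("W", "G"))
  expect_equal(s1@radicalFraction, 1)
})

test_that("nonsense variants are counted but never scored", {
  gm <- GeneModel("ATGCGTTGG", "g")
  v <- parseHgvsp(c("p.R2K", "p.W3*"))
  coh <- observedCohort(gm, v)
  tabv <- variants(coh)
  expect_true(is.na(tabv$score[tabv$kind == "nonsense"]))
  s <- summarizeCohort(coh)
  expect_equal(s@nMissense, 1L)
  expect_equal(s@nNonsense, 1L)
  expect_equal(s@meanScore, 2)

  onlyNon <- observedCohort(gm, parseHgvsp("p.W3*"))
  expect_error(summarizeCohort(onlyNon), "no missense")
})

test_that("summaries are invariant to input row order and exactly integer-consistent", {
  gm <- makeToyGene(L = 80, seed = 5)
  spec <- syntheticSpec(L = 80, N = 60, seed = 9, nonsenseRate = 0)
  maf <- makeCohort(spec, gm)
  coh <- cohortFromMafDf(gm, maf)
  dm <- DomainMap("toygene", data.frame(domain = c("N1", "C1"),
                                        start = c(1, 41), end = c(30, 80)))
  s <- summarizeCohort(coh, dm)

  shuffled <- maf[sample(nrow(maf)), ]
  s2 <- summarizeCohort(cohortFromMafDf(gm, shuffled), dm)
  expect_equal(s@meanScore, s2@meanScore)
  expect_equal(s@radicalFraction, s2@radicalFraction)
  expect_equal(s@perDomain, s2@perDomain)

  ## exact lattice arithmetic and per-domain consistency
  sc <- variants(coh)$score[variants(coh)$kind == "missense"]
  expect_identical(s@radicalFraction, sum(sc <= 0) / length(sc))
  expect_equal(sum(s@perDomain$count), s@nMissense)
  expect_equal(sum(s@perDomain$fraction), 1)
})
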