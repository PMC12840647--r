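#' @import methods
NULL

## Standard one-letter amino-acid alphabet (BLOSUM62 order) and the STOP symbol.
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.STOP <- "*"
.BASES <- c("A", "C", "G", "T")

#' GeneModel: a coding sequence with its codon and protein decomposition
#'
#' A `GeneModel` holds the coding DNA sequence (CDS) of one gene together
#' with its codon decomposition and the translated wild-type protein. The
#' CDS must be a multiple of three over \{A,C,G,T\} with no internal stop
#' codon; a terminal stop codon is stripped at construction and recorded.
#'
#' @slot geneId single gene identifier.
#' @slot cds the coding sequence after stripping a terminal stop codon.
#' @slot codons character vector of 3-mers, one per codon position.
#' @slot protein character vector of one-letter amino acids, `protein[i]`
#'   is the standard-genetic-code translation of `codons[i]`.
#' @slot hadTerminalStop whether the input sequence ended in a stop codon.
#'
#' @seealso [GeneModel()], [loadCDS()]
#' @exportClass GeneModel
setClass("GeneModel",
         slots = c(geneId = "character",
                   cds = "character",
                   codons = "character",
                   protein = "character",
                   hadTerminalStop = "logical"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  L <- length(object@codons)
  if (nchar(object@cds) != 3L * L)
    msg <- c(msg, "cds length must equal 3 * codon count")
  if (length(object@protein) != L)
    msg <- c(msg, "protein length must equal codon count")
  if (grepl("[^ACGT]", object@cds))
    msg <- c(msg, "cds contains characters outside {A,C,G,T}")
  if (L > 0L) {
    expected <- substring(object@cds, 3L * seq_len(L) - 2L, 3L * seq_len(L))
    if (!identical(expected, object@codons))
      msg <- c(msg, "codons do not match the cds")
    tr <- vapply(object@codons, translateCodon, character(1), USE.NAMES = FALSE)
    if (!identical(tr, object@protein))
      msg <- c(msg, "protein is not the translation of the codons")
    if (any(object@protein == .STOP))
      msg <- c(msg, "internal stop codon in protein")
  }
  if (length(msg)) msg else TRUE
})

#' DomainMap: protein-domain intervals for one gene
#'
#' Non-overlapping closed intervals of 1-based residue positions, each
#' labelled with a domain name. Positions not covered by any interval are
#' assigned the reserved name `"Other"` by [assignDomain()].
#'
#' @slot geneId gene identifier the intervals refer to.
#' @slot intervals data.frame with columns `domain`, `start`, `end`
#'   (1-based inclusive).
#'
#' @seealso [DomainMap()], [readDomainMap()], [assignDomain()]
#' @exportClass DomainMap
setClass("DomainMap",
         slots = c(geneId = "character", intervals = "data.frame"))

setValidity("DomainMap", function(object) {
  iv <- object@intervals
  msg <- character()
  need <- c("domain", "start", "end")
  if (!all(need %in% names(iv)))
    return("intervals must have columns domain, start, end")
  if (nrow(iv)) {
    if (any(iv$start < 1L) || any(iv$end < iv$start))
      msg <- c(msg, "intervals must satisfy 1 <= start <= end")
    if (any(iv$domain == "Other"))
      msg <- c(msg, "\"Other\" is reserved for uncovered positions")
    o <- order(iv$start)
    s <- iv$start[o]; e <- iv$end[o]
    if (nrow(iv) > 1L && any(s[-1L] <= e[-nrow(iv)]))
      msg <- c(msg, "intervals overlap")
  }
  if (length(msg)) msg else TRUE
})

#' SubstitutionWeights: the 12 single-base substitution weights
#'
#' Relative weights \eqn{w_{b \to b'}} for each ordered pair of distinct
#' bases, summarising a single-base mutational process (e.g. a
#' transition/transversion bias). All 12 entries must be present and
#' nonnegative with at least one positive; only ratios matter, as event
#' probabilities are normalized downstream.
#'
#' @slot w named numeric vector of length 12; names are `"A>C"`, `"A>G"`,
#'   ... in base order A, C, G, T.
#'
#' @seealso [substitutionWeights()], [readSubstitutionWeights()]
#' @exportClass SubstitutionWeights
setClass("SubstitutionWeights", slots = c(w = "numeric"))

setValidity("SubstitutionWeights", function(object) {
  expected <- substitutionPairNames()
  msg <- character()
  if (length(object@w) != 12L || !identical(sort(names(object@w)), sort(expected)))
    msg <- c(msg, "w must contain exactly the 12 ordered base pairs")
  if (anyNA(object@w) || any(object@w < 0))
    msg <- c(msg, "weights must be nonnegative and non-missing")
  if (length(msg) == 0L && sum(object@w) <= 0)
    msg <- c(msg, "at least one weight must be positive")
  if (length(msg)) msg else TRUE
})

#' NeutralEventTable: the neutral single-nucleotide missense event set
#'
#' Every single-nucleotide substitution in the included codons that changes
#' the encoded amino acid without creating a stop codon, with its raw
#' signature weight, normalized probability, BLOSUM score and radical flag.
#'
#' @slot geneId gene identifier.
#' @slot includedPositions integer codon positions the events were
#'   enumerated over.
#' @slot events data.frame with one row per event: `codon_index`,
#'   `nt_offset` (1-3 within the codon), `from_base`, `to_base`, `wt_aa`,
#'   `mut_aa`, `raw_weight`, `prob`, `score`, `radical`.
#'
#' @seealso [enumerateEvents()], [neutralSummary()], [simulateReplicates()]
#' @exportClass NeutralEventTable
setClass("NeutralEventTable",
         slots = c(geneId = "character",
                   includedPositions = "integer",
                   events = "data.frame"))

setValidity("NeutralEventTable", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("codon_index", "nt_offset", "from_base", "to_base",
            "wt_aa", "mut_aa", "raw_weight", "prob", "score", "radical")
  if (!all(need %in% names(ev)))
    return(paste("events is missing columns:",
                 paste(setdiff(need, names(ev)), collapse = ", ")))
  if (nrow(ev) == 0L)
    return("event table is empty")
  if (abs(sum(ev$prob) - 1) > 1e-12)
    msg <- c(msg, "event probabilities must sum to 1 (tolerance 1e-12)")
  if (any(ev$mut_aa == ev$wt_aa))
    msg <- c(msg, "synonymous events are not allowed")
  if (any(ev$mut_aa == .STOP))
    msg <- c(msg, "stop-gain events are not allowed")
  if (!all(ev$codon_index %in% object@includedPositions))
    msg <- c(msg, "event codon indices outside includedPositions")
  if (length(msg)) msg else TRUE
})

#' ObservedCohort: validated protein variants with BLOSUM scores
#'
#' The observed mutation set for one gene: every variant validated against
#' the wild-type protein, with BLOSUM scores and radical flags attached to
#' the missense variants (nonsense variants are retained but carry `NA`
#' scores, since stop gains are not scoreable).
#'
#' @slot geneId gene identifier.
#' @slot variants data.frame with columns `case_id`, `gene_id`, `position`,
#'   `wt_aa`, `mut_aa`, `kind` (`"missense"` or `"nonsense"`), `raw_label`,
#'   `score`, `radical`.
#'
#' @seealso [observedCohort()], [summarizeCohort()]
#' @exportClass ObservedCohort
setClass("ObservedCohort",
         slots = c(geneId = "character", variants = "data.frame"))

setValidity("ObservedCohort", function(object) {
  v <- object@variants
  need <- c("case_id", "gene_id", "position", "wt_aa", "mut_aa",
            "kind", "raw_label", "score", "radical")
  if (!all(need %in% names(v)))
    return(paste("variants is missing columns:",
                 paste(setdiff(need, names(v)), collapse = ", ")))
  msg <- character()
  mis <- v$kind == "missense"
  if (any(is.na(v$score[mis])))
    msg <- c(msg, "missense variants must carry scores")
  if (any(!is.na(v$score[!mis])))
    msg <- c(msg, "only missense variants may carry scores")
  if (any(v$kind == "nonsense" & v$mut_aa != .STOP) ||
      any(v$kind == "missense" & v$mut_aa == .STOP))
    msg <- c(msg, "kind is nonsense iff mut_aa is the stop symbol")
  if (length(msg)) msg else TRUE
})

#' CohortSummary: observed summary statistics for a cohort
#'
#' @slot geneId gene identifier.
#' @slot nMissense number of missense variants N entering the statistics.
#' @slot nNonsense number of nonsense variants (counted, never scored).
#' @slot meanScore observed mean BLOSUM score over missense variants.
#' @slot radicalFraction fraction of missense variants with a radical
#'   (score at or below threshold) substitution.
#' @slot perDomain data.frame with per-domain `domain`, `count`,
#'   `fraction`, `mean_score` over the missense variants.
#'
#' @seealso [summarizeCohort()]
#' @exportClass CohortSummary
setClass("CohortSummary",
         slots = c(geneId = "character",
                   nMissense = "integer",
                   nNonsense = "integer",
                   meanScore = "numeric",
                   radicalFraction = "numeric",
                   perDomain = "data.frame"))

setValidity("CohortSummary", function(object) {
  msg <- character()
  if (object@radicalFraction < 0 || object@radicalFraction > 1)
    msg <- c(msg, "radicalFraction must lie in [0, 1]")
  pd <- object@perDomain
  if (nrow(pd)) {
    if (sum(pd$count) != object@nMissense)
      msg <- c(msg, "per-domain counts must sum to the missense count")
    if (abs(sum(pd$fraction) - 1) > 1e-9)
      msg <- c(msg, "per-domain fractions must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' ReplicateSet: Monte Carlo neutral replicate summaries
#'
#' @slot M number of replicates.
#' @slot N events drawn per replicate (matched to the observed cohort size).
#' @slot seed RNG seed used (NA when the caller managed the RNG state).
#' @slot meanScores per-replicate mean BLOSUM scores.
#' @slot radicalFractions per-replicate radical fractions.
#'
#' @seealso [simulateReplicates()], [pValues()]
#' @exportClass ReplicateSet
setClass("ReplicateSet",
         slots = c(M = "integer", N = "integer", seed = "integer",
                   meanScores = "numeric", radicalFractions = "numeric"))

setValidity("ReplicateSet", function(object) {
  msg <- character()
  if (length(object@meanScores) != object@M ||
      length(object@radicalFractions) != object@M)
    msg <- c(msg, "summary vectors must have length M")
  if (any(object@radicalFractions < 0 | object@radicalFractions > 1))
    msg <- c(msg, "radical fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' NeutralTest: one-sided Monte Carlo p-values against the neutral model
#'
#' The primary tails test whether the observed cohort is more
#' evolutionarily radical than neutral expectation (lower mean score,
#' higher radical fraction); the opposite tails test the conservative
#' direction and are always reported. Because ties count toward both
#' tails, `p + opposite >= 1`.
#'
#' @slot pMean one-sided p for the mean score (fraction of replicate
#'   means at or below the observed mean).
#' @slot pRad one-sided p for the radical fraction (fraction of replicate
#'   fractions at or above the observed fraction).
#' @slot pMeanOpposite,pRadOpposite the opposite (conservative) tails.
#' @slot mcSe Monte Carlo standard errors for the four estimates.
#' @slot M number of replicates behind the estimates.
#'
#' @seealso [pValues()]
#' @exportClass NeutralTest
setClass("NeutralTest",
         slots = c(pMean = "numeric", pRad = "numeric",
                   pMeanOpposite = "numeric", pRadOpposite = "numeric",
                   mcSe = "numeric", M = "integer"))

setValidity("NeutralTest", function(object) {
  p <- c(object@pMean, object@pRad, object@pMeanOpposite, object@pRadOpposite)
  msg <- character()
  if (any(p < 0 | p > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (object@pMean + object@pMeanOpposite < 1 - 1e-12 ||
      object@pRad + object@pRadOpposite < 1 - 1e-12)
    msg <- c(msg, "tail pairs must satisfy p + opposite >= 1")
  if (length(msg)) msg else TRUE
})

#' GofResult: chi-square and likelihood-ratio G goodness-of-fit result
#'
#' @slot chi2 Pearson chi-square statistic.
#' @slot chi2P upper-tail p-value of `chi2` on `df` degrees of freedom.
#' @slot G likelihood-ratio G statistic (with the 0 log 0 = 0 convention).
#' @slot GP upper-tail p-value of `G`.
#' @slot df degrees of freedom, `k - 1`.
#' @slot k number of categories tested.
#' @slot expected expected counts per category.
#'
#' @seealso [goodnessOfFit()]
#' @exportClass GofResult
setClass("GofResult",
         slots = c(chi2 = "numeric", chi2P = "numeric",
                   G = "numeric", GP = "numeric",
                   df = "integer", k = "integer", expected = "numeric"))

setValidity("GofResult", function(object) {
  msg <- character()
  if (object@chi2 < 0 || object@G < -1e-9)
    msg <- c(msg, "statistics must be nonnegative")
  if (object@df != object@k - 1L)
    msg <- c(msg, "df must equal k - 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic cohort generator
#'
#' @slot L codon count of the synthetic gene (at least 2).
#' @slot N cohort size (missense + nonsense events drawn).
#' @slot seed RNG seed.
#' @slot selectionBeta selection tilt: 0 draws from the neutral event
#'   distribution; positive values bias toward conservative (high-score)
#'   substitutions, negative toward radical ones.
#' @slot weights the [SubstitutionWeights-class] driving the event space.
#' @slot nonsenseRate expected fraction of drawn events replaced by
#'   single-nucleotide stop gains (exercises the nonsense pathway).
#' @slot nCases number of distinct synthetic case identifiers.
#'
#' @seealso [syntheticSpec()], [makeCohort()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         slots = c(L = "integer", N = "integer", seed = "integer",
                   selectionBeta = "numeric", weights = "SubstitutionWeights",
                   nonsenseRate = "numeric", nCases = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@L < 2L) msg <- c(msg, "L must be at least 2")
  if (object@N < 1L) msg <- c(msg, "N must be at least 1")
  if (object@nonsenseRate < 0 || object@nonsenseRate >= 1)
    msg <- c(msg, "nonsenseRate must lie in [0, 1)")
  if (object@nCases < 1L) msg <- c(msg, "nCases must be at least 1")
  if (length(msg)) msg else TRUE
})
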