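#' Enrichment ratio of observed over neutral domain fractions
#'
#' `observedFrac / neutralFrac` where the neutral fraction is positive;
#' `NA` marks the undefined case of a zero neutral fraction (a domain the
#' neutral model cannot reach). A domain with no observed mutations has
#' enrichment 0.
#'
#' @param observedFrac,neutralFrac numeric vectors, recycled.
#' @return numeric vector of ratios.
#' @examples
#' enrichmentRatio(0.3824, 0.1666)  # about 2.3
#' @export
enrichmentRatio <- function(observedFrac, neutralFrac) {
  ifelse(neutralFrac > 0, observedFrac / neutralFrac, NA_real_)
}

#' Domain-level neutral versus observed burden table
#'
#' For each domain (intervals plus `"Other"`): the neutral fraction (sum of
#' event probabilities whose codon falls in the domain), the neutral mean
#' BLOSUM score (probability-weighted within the domain), the observed
#' count/fraction/mean from the cohort summary, and the enrichment ratio.
#' A domain with no observed mutations reports mean 0 with
#' `observed_empty = TRUE` (the mean is undefined, printed as zero by
#' convention); a domain the neutral model cannot reach but that carries
#' observed mutations is flagged (`flagged = TRUE`) rather than erroring.
#'
#' @param table a [NeutralEventTable-class].
#' @param summary a [CohortSummary-class] computed with the same `domains`.
#' @param domains the [DomainMap-class] shared by both inputs.
#' @return data.frame with columns `domain`, `neutral_frac`,
#'   `observed_frac`, `enrichment`, `neutral_mean_score`,
#'   `observed_mean_score`, `observed_count`, `observed_empty`, `flagged`.
#' @export
buildDomainTable <- function(table, summary, domains) {
  stopifnot(is(table, "NeutralEventTable"), is(summary, "CohortSummary"),
            is(domains, "DomainMap"))
  if (table@geneId != summary@geneId)
    stop("event table and cohort summary refer to different genes")
  ev <- table@events
  lev <- domainNames(domains)
  evDom <- factor(assignDomain(domains, ev$codon_index), levels = lev)
  neuFrac <- as.numeric(tapply(ev$prob, evDom, sum, default = 0))
  neuMeanNum <- as.numeric(tapply(ev$prob * ev$score, evDom, sum, default = 0))
  neuMean <- ifelse(neuFrac > 0, neuMeanNum / neuFrac, NA_real_)
  pd <- summary@perDomain
  if (!identical(pd$domain, lev))
    stop("cohort summary was computed with a different domain map")
  out <- data.frame(domain = lev,
                    neutral_frac = neuFrac,
                    observed_frac = pd$fraction,
                    enrichment = ifelse(pd$count == 0 & neuFrac > 0, 0,
                                        enrichmentRatio(pd$fraction, neuFrac)),
                    neutral_mean_score = neuMean,
                    observed_mean_score = ifelse(pd$count > 0,
                                                 pd$mean_score, 0),
                    observed_count = pd$count,
                    observed_empty = pd$count == 0,
                    flagged = neuFrac == 0 & pd$count > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chi-square and likelihood-ratio G goodness-of-fit tests
#'
#' Tests whether observed per-domain mutation counts are consistent with
#' the neutral multinomial expectation. Neutral probabilities are
#' renormalized to sum to one over the tested categories (a proper
#' multinomial null requires it; the renormalization is reported via
#' `message()`). Expected counts are `E_d = N * prob_d`; `chi2 = sum((O -
#' E)^2 / E)` and `G = 2 * sum(O * log(O / E))` with the `0 * log(0) = 0`
#' convention, both referred to the chi-square distribution with `k - 1`
#' degrees of freedom. Categories with zero observed counts stay in the
#' test (their chi-square contribution is `E_d`); any zero expected count
#' is an error instructing the caller to merge categories.
#'
#' @param observedCounts integer vector of per-category observed counts.
#' @param neutralProbs nonnegative per-category neutral probabilities
#'   (renormalized internally).
#' @param N total count; defaults to `sum(observedCounts)` and must match
#'   it.
#' @return a [GofResult-class].
#' @examples
#' goodnessOfFit(c(8, 2), c(0.5, 0.5))
#' @export
goodnessOfFit <- function(observedCounts, neutralProbs,
                          N = sum(observedCounts)) {
  k <- length(observedCounts)
  if (length(neutralProbs) != k)
    stop("observedCounts and neutralProbs must have the same length")
  if (N == 0L) stop("N must be positive")
  if (sum(observedCounts) != N)
    stop("observedCounts must sum to N")
  if (any(neutralProbs < 0) || sum(neutralProbs) <= 0)
    stop("neutralProbs must be nonnegative with a positive sum")
  total <- sum(neutralProbs)
  if (abs(total - 1) > 1e-9)
    message(sprintf("renormalizing neutral probabilities (sum %.6f) over the %d tested categories",
                    total, k))
  probs <- neutralProbs / total
  E <- N * probs
  if (any(E == 0))
    stop("zero expected count in at least one category; merge categories before testing")
  O <- as.numeric(observedCounts)
  chi2 <- sum((O - E)^2 / E)
  gTerms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(gTerms)
  df <- k - 1L
  new("GofResult",
      chi2 = chi2, chi2P = stats::pchisq(chi2, df, lower.tail = FALSE),
      G = G, GP = stats::pchisq(G, df, lower.tail = FALSE),
      df = as.integer(df), k = as.integer(k), expected = E)
}

setMethod("show", "GofResult", function(object) {
  cat(sprintf("Goodness of fit over %d categories (df = %d)\n",
              object@k, object@df))
  cat(sprintf("  chi-square = %.4f, p = %.6g\n", object@chi2, object@chi2P))
  cat(sprintf("  G          = %.4f, p = %.6g\n", object@G, object@GP))
})
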