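#' Enumerate the neutral single-nucleotide missense event set
#'
#' For every included codon, all nine single-nucleotide neighbours are
#' generated (three positions times three alternative bases). Neighbours
#' that leave the amino acid unchanged (synonymous) or create a stop codon
#' (nonsense) are dropped; the survivors form the neutral missense event
#' set. Each event carries the raw signature weight of its base change and
#' a probability normalized over the whole table, so that the event
#' probabilities sum to one. Events whose base change has zero weight are
#' retained with probability zero, keeping the event count a pure function
#' of the codon content.
#'
#' The default event space is restricted to the codon positions that were
#' actually mutated in an observed cohort (pass those as `positions`); use
#' `positions = seq_len(geneLength(gene))` for whole-CDS enumeration.
#'
#' @param gene a [GeneModel-class].
#' @param positions integer codon positions to enumerate over (subset of
#'   `1..L`, non-empty).
#' @param weights a [SubstitutionWeights-class].
#' @param scoreMatrix substitution matrix for scoring (default BLOSUM62).
#' @param radicalThreshold inclusive score cutoff for the radical flag.
#' @return a validated [NeutralEventTable-class].
#' @examples
#' gm <- GeneModel("ATGCGT", "demo")
#' tab <- enumerateEvents(gm, positions = 2L, substitutionWeights("uniform"))
#' nrow(events(tab))  # 6 missense neighbours of CGT
#' @export
enumerateEvents <- function(gene, positions, weights,
                            scoreMatrix = blosum62(), radicalThreshold = 0) {
  stopifnot(is(gene, "GeneModel"), is(weights, "SubstitutionWeights"))
  if (missing(positions) || length(positions) == 0L)
    stop("positions must be a non-empty set of codon indices")
  positions <- sort(unique(as.integer(positions)))
  L <- length(gene@codons)
  if (any(positions < 1L) || any(positions > L))
    stop(sprintf("positions must lie in 1..%d", L))

  ## expand: |positions| codons x 3 offsets x 3 alternative bases
  codon <- gene@codons[positions]
  wt <- gene@protein[positions]
  n <- length(positions)
  idx <- rep(seq_len(n), each = 9L)
  offset <- rep(rep(1:3, each = 3L), times = n)
  cod <- codon[idx]
  from <- substring(cod, offset, offset)
  ## the three bases other than 'from', in fixed A<C<G<T order; within each
  ## (codon, offset) block of 3 rows the rows take the 3 alternatives
  altPool <- matrix(unlist(lapply(.BASES, function(b) setdiff(.BASES, b))),
                    nrow = 3L, dimnames = list(NULL, .BASES))
  alt <- altPool[cbind(rep_len(1:3, 9L * n), match(from, .BASES))]
  mutCodon <- cod
  substr(mutCodon, offset, offset) <- alt
  mut <- .translateCodons(mutCodon)

  keep <- mut != wt[idx] & mut != .STOP
  ev <- data.frame(codon_index = positions[idx][keep],
                   nt_offset = offset[keep],
                   from_base = from[keep],
                   to_base = alt[keep],
                   wt_aa = wt[idx][keep],
                   mut_aa = mut[keep],
                   stringsAsFactors = FALSE)
  if (nrow(ev) == 0L)
    stop("no missense events at the requested positions")
  ev$raw_weight <- .weightFor(weights, ev$from_base, ev$to_base)
  total <- sum(ev$raw_weight)
  if (total <= 0)
    stop("total raw weight over the event set is zero; check the signature weights")
  ev$prob <- ev$raw_weight / total
  ev$score <- as.numeric(blosumScore(ev$wt_aa, ev$mut_aa, scoreMatrix))
  ev$radical <- isRadical(ev$score, radicalThreshold)
  rownames(ev) <- NULL
  new("NeutralEventTable", geneId = gene@geneId,
      includedPositions = positions, events = ev)
}

#' Expected severity under the neutral model
#'
#' The probability-weighted mean BLOSUM score and radical fraction of the
#' neutral event set: `sum(p * S)` and `sum(p * R)`.
#'
#' @param object a [NeutralEventTable-class].
#' @return named list with `meanScore` and `radicalFraction`.
#' @export
setMethod("neutralSummary", "NeutralEventTable", function(object) {
  ev <- object@events
  list(meanScore = sum(ev$prob * ev$score),
       radicalFraction = sum(ev$prob * ev$radical))
})

#' @rdname accessors
setMethod("geneId", "NeutralEventTable", function(x) x@geneId)

#' @rdname accessors
setMethod("events", "NeutralEventTable", function(x) x@events)

#' @rdname accessors
setMethod("eventProbs", "NeutralEventTable", function(x) x@events$prob)

#' @rdname accessors
setMethod("eventScores", "NeutralEventTable", function(x) x@events$score)

#' @rdname accessors
setMethod("includedPositions", "NeutralEventTable",
          function(x) x@includedPositions)

setMethod("show", "NeutralEventTable", function(object) {
  ns <- neutralSummary(object)
  cat(sprintf("NeutralEventTable '%s': %d missense events over %d codon(s)\n",
              object@geneId, nrow(object@events),
              length(object@includedPositions)))
  cat(sprintf("  expected mean score %.3f, expected radical fraction %.3f\n",
              ns$meanScore, ns$radicalFraction))
})
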