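#' Accessors for the core classes
#'
#' `geneId()` returns the gene identifier; `geneLength()` the codon count L;
#' `codons()` and `protein()` the codon and amino-acid decompositions of a
#' [GeneModel-class]; `cds()` the coding sequence; `events()` the event
#' data.frame of a [NeutralEventTable-class]; `eventProbs()` and
#' `eventScores()` its normalized probabilities and BLOSUM scores;
#' `includedPositions()` the codon positions it covers; `variants()` the
#' variant table of an [ObservedCohort-class]; `meanScores()` and
#' `radicalFractions()` the per-replicate summaries of a
#' [ReplicateSet-class].
#'
#' @param x an object of the documented classes.
#' @return the slot contents described above.
#' @name accessors
#' @aliases geneId geneLength codons protein cds events eventProbs
#'   eventScores includedPositions variants meanScores radicalFractions
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("geneLength", function(x) standardGeneric("geneLength"))

#' @rdname accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))

#' @rdname accessors
#' @export
setGeneric("protein", function(x) standardGeneric("protein"))

#' @rdname accessors
#' @export
setGeneric("cds", function(x) standardGeneric("cds"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("eventProbs", function(x) standardGeneric("eventProbs"))

#' @rdname accessors
#' @export
setGeneric("eventScores", function(x) standardGeneric("eventScores"))

#' @rdname accessors
#' @export
setGeneric("includedPositions", function(x) standardGeneric("includedPositions"))

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("meanScores", function(x) standardGeneric("meanScores"))

#' @rdname accessors
#' @export
setGeneric("radicalFractions", function(x) standardGeneric("radicalFractions"))

#' @rdname neutralSummary
#' @export
setGeneric("neutralSummary", function(object) standardGeneric("neutralSummary"))

#' @rdname assignDomain
#' @export
setGeneric("assignDomain", function(map, position) standardGeneric("assignDomain"))

#' @rdname summarizeCohort
#' @export
setGeneric("summarizeCohort",
           function(cohort, domains = NULL) standardGeneric("summarizeCohort"))

#' @rdname pValues
#' @export
setGeneric("pValues", function(reps, muObs, rObs, correction = c("none", "add-one"))
  standardGeneric("pValues"))
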