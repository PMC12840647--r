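#' Generate a random toy gene
#'
#' Builds a random coding sequence of `L` codons starting with ATG, with the
#' remaining codons drawn uniformly from the 61 sense codons so no internal
#' stop can occur. Deterministic under `seed`. The default L = 500 codons is
#' the scale of a mid-sized human oncogene coding sequence.
#'
#' @param L codon count (at least 2; default 500).
#' @param seed integer RNG seed.
#' @param geneId identifier for the gene (default `"toygene"`).
#' @param fastaPath optional path; when given the CDS is also written as a
#'   FASTA record named `geneId`.
#' @return a [GeneModel-class].
#' @examples
#' gm <- makeToyGene(L = 10, seed = 1)
#' @export
makeToyGene <- function(L = 500L, seed, geneId = "toygene", fastaPath = NULL) {
  L <- as.integer(L)
  if (L < 2L) stop("L must be at least 2")
  set.seed(as.integer(seed))
  allCodons <- apply(expand.grid(.BASES, .BASES, .BASES,
                                 stringsAsFactors = FALSE),
                     1L, paste0, collapse = "")
  sense <- allCodons[.translateCodons(allCodons) != .STOP]
  cod <- c("ATG", sample(sense, L - 1L, replace = TRUE))
  gm <- GeneModel(paste(cod, collapse = ""), geneId = geneId)
  if (!is.null(fastaPath)) {
    dss <- Biostrings::DNAStringSet(stats::setNames(gm@cds, geneId))
    Biostrings::writeXStringSet(dss, fastaPath)
  }
  gm
}

#' Specify a synthetic cohort
#'
#' Bundles the generator parameters; see [SyntheticSpec-class] for their
#' meaning. Defaults mirror a study-scale run: a 500-codon gene, a cohort
#' of 200 events, a 5% nonsense admixture, and no selection.
#'
#' @param L codon count of the synthetic gene.
#' @param N cohort size.
#' @param seed integer RNG seed.
#' @param selectionBeta exponential selection tilt on the BLOSUM score
#'   (0 = neutral, negative = radical-shifted, positive =
#'   conservative-shifted).
#' @param weights a [SubstitutionWeights-class].
#' @param nonsenseRate expected fraction of events replaced by stop gains.
#' @param nCases number of distinct case identifiers.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(L = 500L, N = 200L, seed,
                          selectionBeta = 0,
                          weights = substitutionWeights("uniform"),
                          nonsenseRate = 0.05, nCases = N) {
  new("SyntheticSpec", L = as.integer(L), N = as.integer(N),
      seed = as.integer(seed), selectionBeta = as.numeric(selectionBeta),
      weights = weights, nonsenseRate = as.numeric(nonsenseRate),
      nCases = as.integer(nCases))
}

#' Draw a synthetic mutation cohort with controllable selection pressure
#'
#' Draws `N` events from the whole-CDS neutral event table of `gene` with
#' per-event probability proportional to `p_j * exp(selectionBeta * S_j)` —
#' an exponential tilt on the BLOSUM score that reduces to the neutral
#' distribution at `selectionBeta = 0`, shifts mass toward radical
#' (negative-score) substitutions for negative beta, and toward
#' conservative substitutions for positive beta. This one-parameter family
#' is a test fixture for exercising the selection tests, not a biological
#' model of tumour selection. A configurable fraction of events is
#' replaced by single-nucleotide stop gains so readers see nonsense rows.
#'
#' @param spec a [SyntheticSpec-class] (its `L` is ignored when `gene` is
#'   supplied; the gene defines the event space).
#' @param gene the [GeneModel-class] to mutate; defaults to
#'   `makeToyGene(spec@L, spec@seed)`.
#' @param path optional path; when given the cohort is written as a
#'   MAF-lite TSV.
#' @return data.frame in MAF-lite layout (`case_id`, `gene`,
#'   `protein_change`, `variant_class`), one row per event.
#' @export
makeCohort <- function(spec, gene = NULL, path = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (is.null(gene))
    gene <- makeToyGene(spec@L, seed = spec@seed)
  L <- length(gene@codons)
  tab <- enumerateEvents(gene, seq_len(L), spec@weights)
  ev <- tab@events
  set.seed(spec@seed)
  tilt <- ev$prob * exp(spec@selectionBeta * ev$score)
  if (sum(tilt) <= 0) stop("selection tilt removed all event probability")
  drawn <- sample.int(nrow(ev), spec@N, replace = TRUE, prob = tilt)
  caseIds <- sprintf("case_%04d", sample.int(spec@nCases, spec@N,
                                             replace = TRUE))
  out <- data.frame(case_id = caseIds,
                    gene = gene@geneId,
                    protein_change = formatHgvsp(ev$codon_index[drawn],
                                                 ev$wt_aa[drawn],
                                                 ev$mut_aa[drawn]),
                    variant_class = "missense",
                    stringsAsFactors = FALSE)
  ## replace a random subset with single-nucleotide stop gains
  nNon <- stats::rbinom(1L, spec@N, spec@nonsenseRate)
  if (nNon > 0L) {
    stops <- .enumerateStopGains(gene)
    if (nrow(stops)) {
      rows <- sample.int(spec@N, nNon)
      pick <- sample.int(nrow(stops), nNon, replace = TRUE)
      out$protein_change[rows] <- formatHgvsp(stops$codon_index[pick],
                                              stops$wt_aa[pick], .STOP)
      out$variant_class[rows] <- "nonsense"
    }
  }
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

## all single-nucleotide stop-gain events of a gene (fixture support)
.enumerateStopGains <- function(gene) {
  L <- length(gene@codons)
  idx <- rep(seq_len(L), each = 9L)
  offset <- rep(rep(1:3, each = 3L), times = L)
  cod <- gene@codons[idx]
  from <- substring(cod, offset, offset)
  altPool <- matrix(unlist(lapply(.BASES, function(b) setdiff(.BASES, b))),
                    nrow = 3L, dimnames = list(NULL, .BASES))
  alt <- altPool[cbind(rep_len(1:3, 9L * L), match(from, .BASES))]
  mutCodon <- cod
  substr(mutCodon, offset, offset) <- alt
  mut <- .translateCodons(mutCodon)
  keep <- mut == .STOP
  data.frame(codon_index = idx[keep], wt_aa = gene@protein[idx[keep]],
             stringsAsFactors = FALSE)
}
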