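#' Translate a single codon with the standard genetic code
#'
#' @param codon a 3-character string over \{A,C,G,T\} (case-insensitive).
#' @return the one-letter amino acid, or `"*"` for a stop codon.
#' @examples
#' translateCodon("TGG")  # "W"
#' translateCodon("TAG")  # "*"
#' @export
translateCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L)
    stop("codon must be a single string")
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop(sprintf("invalid codon '%s': must be 3 bases over {A,C,G,T}", codon))
  unname(Biostrings::GENETIC_CODE[[codon]])
}

## vectorized translation of many codons (internal fast path)
.translateCodons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Construct a GeneModel from a coding sequence
#'
#' Normalizes the sequence to uppercase, checks the alphabet and that the
#' length is divisible by three, strips a terminal stop codon if present,
#' and errors on any internal stop codon (a CDS with internal stops does
#' not define a wild-type protein).
#'
#' @param cds coding DNA sequence (string over A/C/G/T, case-insensitive).
#' @param geneId gene identifier to attach.
#' @return a validated [GeneModel-class].
#' @examples
#' gm <- GeneModel("ATGCGT", "demo")
#' protein(gm)  # "M" "R"
#' @export
GeneModel <- function(cds, geneId = "gene") {
  if (!is.character(cds) || length(cds) != 1L)
    stop("cds must be a single string")
  cds <- toupper(gsub("[ \t\r\n]", "", cds))
  if (grepl("[^ACGT]", cds)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", cds), "")[[1]])
    stop(sprintf("CDS for '%s' contains non-ACGT character(s): %s",
                 geneId, paste(bad, collapse = ", ")))
  }
  n <- nchar(cds)
  if (n == 0L) stop("CDS is empty")
  if (n %% 3L != 0L)
    stop(sprintf("CDS length %d for '%s' is not divisible by 3", n, geneId))
  L <- n %/% 3L
  cod <- substring(cds, 3L * seq_len(L) - 2L, 3L * seq_len(L))
  aa <- .translateCodons(cod)
  hadStop <- FALSE
  if (aa[L] == .STOP) {
    hadStop <- TRUE
    cod <- cod[-L]; aa <- aa[-L]
    cds <- substr(cds, 1L, 3L * (L - 1L))
    L <- L - 1L
    if (L == 0L) stop("CDS consists only of a stop codon")
  }
  internal <- which(aa == .STOP)
  if (length(internal))
    stop(sprintf("internal stop codon at codon index %s in '%s'",
                 paste(internal, collapse = ", "), geneId))
  new("GeneModel", geneId = geneId, cds = cds, codons = cod,
      protein = aa, hadTerminalStop = hadStop)
}

#' Load a gene's coding sequence from a FASTA file
#'
#' Reads a (single- or multi-record) FASTA file, selects the record whose
#' identifier (first whitespace-delimited token of the header, or the full
#' header) matches `geneId`, and builds a [GeneModel-class]. When a protein
#' FASTA is supplied as a cross-check, the translation of the CDS must
#' match its sequence exactly (a terminal `*` in either is ignored).
#'
#' @param fastaPath path to the CDS FASTA file.
#' @param geneId identifier of the record to load.
#' @param proteinFasta optional path to a protein FASTA used to verify the
#'   translation; a mismatch is an error.
#' @return a validated [GeneModel-class].
#' @export
loadCDS <- function(fastaPath, geneId, proteinFasta = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  idx <- .matchFastaRecord(names(seqs), geneId, fastaPath)
  gm <- GeneModel(as.character(seqs[[idx]]), geneId = geneId)
  if (!is.null(proteinFasta)) {
    prot <- Biostrings::readAAStringSet(proteinFasta)
    pidx <- .matchFastaRecord(names(prot), geneId, proteinFasta)
    ref <- sub("\\*$", "", as.character(prot[[pidx]]))
    got <- paste(gm@protein, collapse = "")
    if (!identical(got, ref))
      stop(sprintf(paste0("translated CDS for '%s' does not match the ",
                          "protein FASTA (%d aa translated vs %d aa in file)"),
                   geneId, nchar(got), nchar(ref)))
  }
  gm
}

.matchFastaRecord <- function(headers, geneId, path) {
  tokens <- sub("\\s.*$", "", headers)
  idx <- which(tokens == geneId | headers == geneId)
  if (length(idx) == 0L)
    stop(sprintf("no FASTA record matching id '%s' in %s", geneId, path))
  if (length(idx) > 1L)
    stop(sprintf("multiple FASTA records match id '%s' in %s", geneId, path))
  idx
}

#' @rdname accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname accessors
setMethod("geneLength", "GeneModel", function(x) length(x@codons))

#' @rdname accessors
setMethod("codons", "GeneModel", function(x) x@codons)

#' @rdname accessors
setMethod("protein", "GeneModel", function(x) x@protein)

#' @rdname accessors
setMethod("cds", "GeneModel", function(x) x@cds)

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s': %d codons (%d nt)%s\n",
              object@geneId, length(object@codons), nchar(object@cds),
              if (object@hadTerminalStop) ", terminal stop stripped" else ""))
  L <- length(object@protein)
  head <- paste(object@protein[seq_len(min(L, 30L))], collapse = "")
  cat(sprintf("  protein: %s%s\n", head, if (L > 30L) "..." else ""))
})
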