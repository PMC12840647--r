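# Brute-force oracle for the neutral event set: mutate every nucleotide of
# the raw CDS string, re-translate the WHOLE sequence with Biostrings, and
# classify each neighbour by comparing proteins. Independent of the
# package's per-codon enumeration path.
bruteForceEvents <- function(gene, positions, weights) {
  cdsStr <- cds(gene)
  n <- nchar(cdsStr)
  wtProt <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cdsStr), no.init.codon = TRUE)), "")[[1]]
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (nt in seq_len(n)) {
    ci <- (nt - 1L) %/% 3L + 1L
    if (!(ci %in% positions)) next
    b <- substr(cdsStr, nt, nt)
    for (bp in setdiff(bases, b)) {
      mut <- cdsStr
      substr(mut, nt, nt) <- bp
      mutProt <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(mut), no.init.codon = TRUE)), "")[[1]]
      stopifnot(all(mutProt[-ci] == wtProt[-ci]))
      rows[[length(rows) + 1L]] <- data.frame(
        codon_index = ci, nt_offset = (nt - 1L) %% 3L + 1L,
        from_base = b, to_base = bp,
        wt_aa = wtProt[ci], mut_aa = mutProt[ci],
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  ev <- all[all$mut_aa != all$wt_aa & all$mut_aa != "*", , drop = FALSE]
  ev$raw_weight <- unname(weights@w[paste0(ev$from_base, ">", ev$to_base)])
  ev$prob <- ev$raw_weight / sum(ev$raw_weight)
  ev$score <- as.numeric(blosum62()[cbind(ev$wt_aa, ev$mut_aa)])
  ev$radical <- ev$score <= 0
  rownames(ev) <- NULL
  attr(ev, "neighbour_classes") <- data.frame(
    codon_index = all$codon_index,
    class = ifelse(all$mut_aa == "*", "stop",
                   ifelse(all$mut_aa == all$wt_aa, "synonymous", "missense")),
    stringsAsFactors = FALSE)
  ev
}

# canonical row order so oracle and implementation can be compared
sortEvents <- function(ev) {
  ev <- ev[order(ev$codon_index, ev$nt_offset, ev$to_base), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

randomWeights <- function(seed) {
  set.seed(seed)
  substitutionWeights(values = stats::setNames(stats::runif(12, 0.1, 3),
                                               substitutionPairNames()))
}

# hand-build a NeutralEventTable from scores and probabilities (for
# degenerate Monte Carlo cases the enumerator cannot produce)
manualEventTable <- function(scores, probs, geneId = "manual") {
  k <- length(scores)
  ev <- data.frame(codon_index = seq_len(k), nt_offset = 1L,
                   from_base = "A", to_base = "C",
                   wt_aa = "K", mut_aa = "Q",
                   raw_weight = probs, prob = probs,
                   score = scores, radical = scores <= 0,
                   stringsAsFactors = FALSE)
  new("NeutralEventTable", geneId = geneId,
      includedPositions = seq_len(k), events = ev)
}

writeMafLite <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeFasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(mapply(function(id, s) c(paste0(">", id), s),
                         names(seqs), seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# summarize a synthetic MAF-lite data.frame without touching disk
cohortFromMafDf <- function(gene, df, ...) {
  v <- parseHgvsp(df$protein_change)
  v$case_id <- df$case_id
  v$gene_id <- df$gene
  observedCohort(gene, v, ...)
}
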