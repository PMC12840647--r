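.AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
               Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
               Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
               Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
               Ter = "*")

.parseResidueToken <- function(token, label) {
  if (nchar(token) == 1L) {
    up <- toupper(token)
    if (up %in% c(.AA_ALPHABET, .STOP)) return(up)
  } else if (nchar(token) == 3L) {
    key <- paste0(toupper(substr(token, 1, 1)), tolower(substr(token, 2, 3)))
    if (key %in% names(.AA3_TO_1)) return(unname(.AA3_TO_1[key]))
  }
  stop(errorCondition(
    sprintf("cannot parse residue token '%s' in protein change '%s'",
            token, label),
    class = c("hgvspParseError", "error", "condition")))
}

#' Parse an HGVSp-style protein-change label
#'
#' Accepts labels such as `"R273H"`, `"p.R273H"`, `"p.Arg273His"` and
#' `"Q136*"` / `"p.Gln136Ter"`: an optional `p.` prefix, one- or
#' three-letter residue codes, a 1-based residue position, and `*`/`Ter`
#' for a stop gain. Synonymous labels (wild-type equals mutant) are
#' rejected with a condition of class `synonymousVariantError`;
#' unparseable labels raise `hgvspParseError` carrying the raw string.
#'
#' @param label protein-change string(s); vectorized.
#' @return a data.frame with one row per label and columns `position`,
#'   `wt_aa`, `mut_aa`, `kind` (`"missense"`/`"nonsense"`), `raw_label`.
#' @examples
#' parseHgvsp("p.R273H")
#' parseHgvsp("Q136*")
#' @export
parseHgvsp <- function(label) {
  if (!is.character(label) || length(label) < 1L)
    stop("label must be a character vector")
  one <- function(lab) {
    m <- regmatches(lab, regexec(
      "^(?:p\\.)?([A-Za-z]{1,3})([0-9]+)(\\*|[A-Za-z]{1,3})$", lab))[[1]]
    if (length(m) == 0L)
      stop(errorCondition(
        sprintf("unparseable protein change label: '%s'", lab),
        class = c("hgvspParseError", "error", "condition")))
    wt <- .parseResidueToken(m[2], lab)
    mut <- .parseResidueToken(m[4], lab)
    if (wt == .STOP)
      stop(errorCondition(
        sprintf("wild-type residue cannot be a stop in '%s'", lab),
        class = c("hgvspParseError", "error", "condition")))
    if (wt == mut)
      stop(errorCondition(
        sprintf("synonymous protein change rejected: '%s'", lab),
        class = c("synonymousVariantError", "error", "condition")))
    data.frame(position = as.integer(m[3]), wt_aa = wt, mut_aa = mut,
               kind = if (mut == .STOP) "nonsense" else "missense",
               raw_label = lab, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(label, one))
}

#' Format a variant as an HGVSp-style label
#'
#' Inverse of [parseHgvsp()] for one-letter output: `formatHgvsp(273, "R",
#' "H")` gives `"p.R273H"`.
#'
#' @param position 1-based residue position(s).
#' @param wt_aa,mut_aa one-letter residues (`"*"` for a stop gain).
#' @param prefix prepend `"p."` (default TRUE).
#' @return character vector of labels.
#' @export
formatHgvsp <- function(position, wt_aa, mut_aa, prefix = TRUE) {
  paste0(if (prefix) "p." else "", wt_aa, position, mut_aa)
}

#' Validate variants against a gene model
#'
#' Checks every variant's position against the gene length and its stated
#' wild-type residue against the translated protein. By default any
#' failure is an error naming the expected versus stated residue; with
#' `onMismatch = "skip"` failing rows are dropped with a warning (public
#' mutation tables mix transcript isoforms, so cohort-level runs may
#' prefer skipping), and the number of skips is attached as attribute
#' `n_skipped`.
#'
#' @param gene a [GeneModel-class].
#' @param variants data.frame as returned by [parseHgvsp()] or
#'   [readMafLite()] (columns `position`, `wt_aa` at minimum).
#' @param onMismatch `"error"` (default) or `"skip"`.
#' @return the validated variants, unchanged apart from dropped rows in
#'   skip mode.
#' @export
validateVariants <- function(gene, variants, onMismatch = c("error", "skip")) {
  onMismatch <- match.arg(onMismatch)
  stopifnot(is(gene, "GeneModel"), is.data.frame(variants))
  if (nrow(variants) == 0L) return(variants)
  L <- length(gene@codons)
  problems <- character(nrow(variants))
  oob <- variants$position < 1L | variants$position > L
  problems[oob] <- sprintf("position %d out of range 1..%d",
                           variants$position[oob], L)
  inr <- which(!oob)
  expect <- gene@protein[variants$position[inr]]
  bad <- expect != variants$wt_aa[inr]
  problems[inr[bad]] <- sprintf(
    "wild-type mismatch at position %d: gene has %s, variant states %s",
    variants$position[inr[bad]], expect[bad], variants$wt_aa[inr[bad]])
  failing <- which(nzchar(problems))
  if (length(failing) == 0L) {
    attr(variants, "n_skipped") <- 0L
    return(variants)
  }
  detail <- sprintf("%s ('%s')", problems[failing],
                    if ("raw_label" %in% names(variants))
                      variants$raw_label[failing] else "")
  if (onMismatch == "error")
    stop(sprintf("variant validation failed for gene '%s':\n  %s",
                 gene@geneId, paste(detail, collapse = "\n  ")))
  warning(sprintf("skipped %d variant(s) failing validation for '%s':\n  %s",
                  length(failing), gene@geneId,
                  paste(detail, collapse = "\n  ")))
  out <- variants[-failing, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(failing)
  out
}
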