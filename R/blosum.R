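## BLOSUM62 over the 20 standard amino acids, embedded as text so the
## package carries its own copy of the canonical published matrix.
.BLOSUM62_TEXT <- "
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0
R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3
N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3
D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3
C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1
Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2
E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2
G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3
H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3
I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3
L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1
K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2
M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1
F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2
S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0
W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3
Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1
V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4
"

.parseMatrixText <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(rows, `[`, character(1), 1L)
  m <- t(vapply(rows, function(r) as.integer(r[-1L]), integer(length(header))))
  dimnames(m) <- list(rn, header)
  m
}

.blosum62 <- .parseMatrixText(.BLOSUM62_TEXT)

#' The BLOSUM62 substitution matrix
#'
#' Returns the 20x20 symmetric BLOSUM62 log-odds matrix over the standard
#' amino-acid alphabet, as embedded in the package. Higher scores indicate
#' more evolutionarily conservative substitutions.
#'
#' @return integer matrix with amino-acid dimnames.
#' @examples
#' blosum62()["R", "K"]  # 2
#' @export
blosum62 <- function() .blosum62

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix format used by NCBI (comment lines starting
#' with `#`, a header row of residue letters, one labelled row per
#' residue), restricted to the 20 standard amino acids. An extension point
#' for scoring with matrices other than the embedded BLOSUM62.
#'
#' @param path path to the matrix file.
#' @return integer matrix over the standard amino-acid alphabet.
#' @export
readScoreMatrix <- function(path) {
  m <- .parseMatrixText(paste(readLines(path), collapse = "\n"))
  keep <- intersect(rownames(m), .AA_ALPHABET)
  if (length(keep) != 20L)
    stop(sprintf("matrix in %s does not cover the 20 standard amino acids",
                 path))
  m <- m[.AA_ALPHABET, .AA_ALPHABET]
  if (!isSymmetric(unname(m)))
    stop(sprintf("matrix in %s is not symmetric", path))
  m
}

#' Score an amino-acid substitution
#'
#' Looks up the substitution score for wild-type/mutant residue pairs.
#' Stop symbols are not scoreable (the neutral event set excludes stop
#' gains) and raise an error, as do nonstandard residues.
#'
#' @param wt_aa,mut_aa one-letter amino acids; vectorized and recycled.
#' @param matrix substitution matrix (default the embedded BLOSUM62).
#' @return integer score(s).
#' @examples
#' blosumScore("R", "K")  # 2
#' blosumScore("W", "W")  # 11
#' @export
blosumScore <- function(wt_aa, mut_aa, matrix = blosum62()) {
  bad <- !(wt_aa %in% rownames(matrix)) | !(mut_aa %in% colnames(matrix))
  if (any(bad)) {
    off <- unique(c(wt_aa[!(wt_aa %in% rownames(matrix))],
                    mut_aa[!(mut_aa %in% colnames(matrix))]))
    stop(sprintf("cannot score residue(s): %s (stop and nonstandard residues have no substitution score)",
                 paste(off, collapse = ", ")))
  }
  matrix[cbind(wt_aa, mut_aa)]
}

#' Radical-substitution indicator
#'
#' A substitution is called radical (evolutionarily divergent) when its
#' score is at or below the threshold: `score <= threshold`, with the
#' default threshold 0 so that a score of exactly 0 counts as radical.
#'
#' @param score numeric score(s).
#' @param threshold inclusive cutoff (default 0).
#' @return logical vector.
#' @examples
#' isRadical(c(0, -2, 1))  # TRUE TRUE FALSE
#' @export
isRadical <- function(score, threshold = 0) {
  if (!is.numeric(score)) stop("score must be numeric")
  score <= threshold
}
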