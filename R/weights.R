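#' Names of the 12 ordered base substitutions
#'
#' @return character vector `"A>C"`, `"A>G"`, ..., `"T>G"` in base order.
#' @export
substitutionPairNames <- function() {
  pairs <- expand.grid(to = .BASES, from = .BASES,
                       stringsAsFactors = FALSE)[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, ]
  sort(paste0(pairs$from, ">", pairs$to))
}

.TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Build single-base substitution weights
#'
#' Two presets ship with the package: `"uniform"` (all 12 substitutions
#' equally weighted) and `"titv"` (transitions weighted `kappa` times the
#' transversions, default kappa = 2). Both are generic placeholders for a
#' mutational process, not estimates for any particular tumour type; a
#' cohort-specific 12-entry signature can be supplied via `values` or
#' loaded with [readSubstitutionWeights()].
#'
#' @param preset `"uniform"` or `"titv"`; ignored when `values` is given.
#' @param kappa transition/transversion weight ratio for the `"titv"`
#'   preset.
#' @param values optional named numeric vector with exactly the 12 names
#'   from [substitutionPairNames()].
#' @return a validated [SubstitutionWeights-class].
#' @examples
#' substitutionWeights("titv", kappa = 2)
#' @export
substitutionWeights <- function(preset = c("uniform", "titv"), kappa = 2,
                                values = NULL) {
  nm <- substitutionPairNames()
  if (!is.null(values)) {
    if (is.null(names(values)))
      stop("values must be named by substitution pair, e.g. 'A>G'")
    missing <- setdiff(nm, names(values))
    extra <- setdiff(names(values), nm)
    if (length(missing) || length(extra))
      stop(sprintf("values must contain exactly the 12 pairs; missing: %s; unexpected: %s",
                   paste(missing, collapse = ", "),
                   paste(extra, collapse = ", ")))
    w <- as.numeric(values[nm]); names(w) <- nm
    return(new("SubstitutionWeights", w = w))
  }
  preset <- match.arg(preset)
  w <- rep(1, 12); names(w) <- nm
  if (preset == "titv") {
    if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be positive")
    w[.TRANSITIONS] <- kappa
  }
  new("SubstitutionWeights", w = w)
}

#' Read substitution weights from TSV or YAML
#'
#' TSV files need columns `from`, `to`, `weight` (12 rows, one per ordered
#' base pair); YAML files map `"A>G"`-style keys to weights. Completeness
#' is validated strictly: all 12 pairs, no duplicates, no extras.
#'
#' @param path file path (`.yml`/`.yaml` parsed as YAML, else tab-separated).
#' @return a validated [SubstitutionWeights-class].
#' @export
readSubstitutionWeights <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    values <- unlist(doc)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("from", "to", "weight")
    if (!all(need %in% names(tab)))
      stop(sprintf("weights table %s must have columns: %s", path,
                   paste(need, collapse = ", ")))
    values <- stats::setNames(tab$weight, paste0(tab$from, ">", tab$to))
  }
  if (anyDuplicated(names(values)))
    stop(sprintf("duplicate substitution pairs in %s", path))
  substitutionWeights(values = values)
}

#' Look up weights for from/to base vectors
#' @keywords internal
.weightFor <- function(weights, from, to) {
  unname(weights@w[paste0(from, ">", to)])
}

setMethod("show", "SubstitutionWeights", function(object) {
  cat("SubstitutionWeights (12 single-base substitution weights):\n")
  print(object@w)
})
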