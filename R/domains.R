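#' Construct a DomainMap
#'
#' @param geneId gene identifier.
#' @param intervals data.frame with columns `domain`, `start`, `end`
#'   (1-based inclusive residue coordinates; intervals must not overlap).
#' @return a validated [DomainMap-class].
#' @examples
#' dm <- DomainMap("TP53", data.frame(domain = "DBD", start = 94, end = 292))
#' assignDomain(dm, c(273, 10))
#' @export
DomainMap <- function(geneId, intervals) {
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  new("DomainMap", geneId = geneId,
      intervals = intervals[, c("domain", "start", "end")])
}

#' Read a domain map from TSV or YAML
#'
#' TSV files need columns `gene_id`, `domain`, `start`, `end`; YAML files
#' map gene ids to lists of `{domain, start, end}` records. Coordinates are
#' 1-based inclusive residue positions.
#'
#' @param path file path (`.yml`/`.yaml` parsed as YAML, anything else as
#'   tab-separated).
#' @param geneId gene whose intervals to extract.
#' @return a [DomainMap-class].
#' @export
readDomainMap <- function(path, geneId) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc[[geneId]]))
      stop(sprintf("no domain entries for gene '%s' in %s", geneId, path))
    iv <- do.call(rbind, lapply(doc[[geneId]], function(r)
      data.frame(domain = r$domain, start = r$start, end = r$end,
                 stringsAsFactors = FALSE)))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "domain", "start", "end")
    if (!all(need %in% names(tab)))
      stop(sprintf("domain table %s must have columns: %s", path,
                   paste(need, collapse = ", ")))
    iv <- tab[tab$gene_id == geneId, c("domain", "start", "end")]
    if (nrow(iv) == 0L)
      stop(sprintf("no domain entries for gene '%s' in %s", geneId, path))
  }
  DomainMap(geneId, iv)
}

#' Assign residue positions to protein domains
#'
#' Every position maps to exactly one name: the covering interval's domain,
#' or the reserved name `"Other"` when no interval covers it.
#'
#' @param map a [DomainMap-class].
#' @param position integer vector of 1-based residue positions.
#' @return character vector of domain names, same length as `position`.
#' @export
setMethod("assignDomain", "DomainMap", function(map, position) {
  if (any(position < 1L)) stop("positions must be >= 1")
  iv <- map@intervals
  out <- rep("Other", length(position))
  for (r in seq_len(nrow(iv))) {
    hit <- position >= iv$start[r] & position <= iv$end[r]
    out[hit] <- iv$domain[r]
  }
  out
})

#' All domain names of a map, including "Other"
#'
#' @param map a [DomainMap-class].
#' @return character vector of interval names followed by `"Other"`.
#' @export
domainNames <- function(map) c(map@intervals$domain, "Other")

setMethod("show", "DomainMap", function(object) {
  cat(sprintf("DomainMap '%s' with %d interval(s):\n",
              object@geneId, nrow(object@intervals)))
  for (r in seq_len(nrow(object@intervals)))
    cat(sprintf("  %s: %d-%d\n", object@intervals$domain[r],
                object@intervals$start[r], object@intervals$end[r]))
})
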