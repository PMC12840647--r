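#' Read a MAF-lite cohort mutation table
#'
#' Reads a tab-separated table with header columns `case_id`, `gene`,
#' `protein_change`, `variant_class`, keeps the rows for `geneId` whose
#' class is `missense` or `nonsense`, and parses the protein changes with
#' [parseHgvsp()]. Unparseable labels are skipped per row with a warning
#' and a final skip count (attached as attribute `n_skipped`). Duplicate
#' `(case_id, protein_change)` rows are collapsed to one event per case by
#' default — identical calls from paired biospecimens should not be double
#' counted — while `perBiospecimen = TRUE` keeps them. A variant shared by
#' many cases still contributes once per case: cohort frequency is the
#' quantity of interest.
#'
#' Standard GDC MAF column names (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `HGVSp_Short`, `Variant_Classification`, with classes
#' `Missense_Mutation`/`Nonsense_Mutation`) are mapped onto the MAF-lite
#' schema automatically.
#'
#' @param path path to the tab-separated file.
#' @param geneId gene to extract.
#' @param perBiospecimen keep duplicate (case, protein change) rows.
#' @return data.frame of variants in file order with columns `case_id`,
#'   `gene_id`, `position`, `wt_aa`, `mut_aa`, `kind`, `raw_label`.
#' @export
readMafLite <- function(path, geneId, perBiospecimen = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  gdc <- c(case_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
           protein_change = "HGVSp_Short", variant_class = "Variant_Classification")
  if (all(gdc %in% names(tab))) {
    for (lite in names(gdc)) tab[[lite]] <- tab[[gdc[lite]]]
    tab$variant_class <- c(Missense_Mutation = "missense",
                           Nonsense_Mutation = "nonsense")[tab$variant_class]
    tab$variant_class[is.na(tab$variant_class)] <- "other"
  }
  need <- c("case_id", "gene", "protein_change", "variant_class")
  if (!all(need %in% names(tab)))
    stop(sprintf("MAF-lite file %s is missing column(s): %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  tab <- tab[tab$gene == geneId &
               tab$variant_class %in% c("missense", "nonsense"), ,
             drop = FALSE]
  if (!perBiospecimen)
    tab <- tab[!duplicated(tab[, c("case_id", "protein_change")]), ,
               drop = FALSE]
  parsed <- vector("list", nrow(tab))
  skipped <- character()
  for (r in seq_len(nrow(tab))) {
    p <- tryCatch(parseHgvsp(tab$protein_change[r]), error = function(e) e)
    if (inherits(p, "error")) {
      skipped <- c(skipped, sprintf("row for case %s: %s", tab$case_id[r],
                                    conditionMessage(p)))
    } else {
      p$case_id <- tab$case_id[r]
      p$gene_id <- geneId
      parsed[[r]] <- p
    }
  }
  if (length(skipped))
    warning(sprintf("skipped %d unparseable protein change(s) in %s:\n  %s",
                    length(skipped), path, paste(skipped, collapse = "\n  ")))
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  out <- if (length(parsed)) do.call(rbind, parsed) else
    data.frame(position = integer(), wt_aa = character(),
               mut_aa = character(), kind = character(),
               raw_label = character(), case_id = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  out <- out[, c("case_id", "gene_id", "position", "wt_aa", "mut_aa",
                 "kind", "raw_label")]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(skipped)
  out
}

#' Build an ObservedCohort from parsed variants
#'
#' Validates the variants against the gene model (see
#' [validateVariants()]), scores the missense variants with the
#' substitution matrix and attaches radical flags. Nonsense variants are
#' retained with `NA` scores: they are counted but never enter the BLOSUM
#' statistics, matching the neutral event set which excludes stop gains.
#'
#' @param gene a [GeneModel-class].
#' @param variants data.frame from [readMafLite()] or [parseHgvsp()]
#'   (with `case_id`/`gene_id` columns added).
#' @param onMismatch `"error"` (default) or `"skip"`; see
#'   [validateVariants()].
#' @param scoreMatrix substitution matrix (default BLOSUM62).
#' @param radicalThreshold inclusive score cutoff for the radical flag.
#' @return a validated [ObservedCohort-class].
#' @export
observedCohort <- function(gene, variants, onMismatch = c("error", "skip"),
                           scoreMatrix = blosum62(), radicalThreshold = 0) {
  if (!"case_id" %in% names(variants)) variants$case_id <- "case"
  if (!"gene_id" %in% names(variants)) variants$gene_id <- gene@geneId
  v <- validateVariants(gene, variants, onMismatch)
  v$score <- NA_real_
  v$radical <- NA
  mis <- v$kind == "missense"
  if (any(mis)) {
    v$score[mis] <- as.numeric(
      blosumScore(v$wt_aa[mis], v$mut_aa[mis], scoreMatrix))
    v$radical[mis] <- isRadical(v$score[mis], radicalThreshold)
  }
  new("ObservedCohort", geneId = gene@geneId,
      variants = v[, c("case_id", "gene_id", "position", "wt_aa", "mut_aa",
                       "kind", "raw_label", "score", "radical")])
}

#' Observed cohort summary statistics
#'
#' Computes the observed mean BLOSUM score and radical fraction over the
#' missense variants, plus per-domain counts, fractions and mean scores
#' when a [DomainMap-class] is supplied (all missense positions are
#' assigned to a domain, uncovered positions to `"Other"`). Nonsense
#' variants are excluded from the score statistics and reported only as a
#' count.
#'
#' @param cohort an [ObservedCohort-class] with at least one missense
#'   variant.
#' @param domains optional [DomainMap-class]; when `NULL` all variants
#'   fall in a single `"Other"` bucket.
#' @return a [CohortSummary-class].
#' @export
setMethod("summarizeCohort", "ObservedCohort", function(cohort, domains = NULL) {
  v <- cohort@variants
  mis <- v[v$kind == "missense", , drop = FALSE]
  N <- nrow(mis)
  if (N == 0L)
    stop(sprintf("cohort for '%s' contains no missense variants; nothing to summarize",
                 cohort@geneId))
  dom <- if (is.null(domains)) rep("Other", N) else
    assignDomain(domains, mis$position)
  levelsD <- if (is.null(domains)) "Other" else domainNames(domains)
  dom <- factor(dom, levels = levelsD)
  counts <- as.integer(table(dom))
  means <- tapply(mis$score, dom, mean)
  pd <- data.frame(domain = levelsD,
                   count = counts,
                   fraction = counts / N,
                   mean_score = ifelse(counts > 0, as.numeric(means), NA_real_),
                   stringsAsFactors = FALSE)
  rownames(pd) <- NULL
  new("CohortSummary", geneId = cohort@geneId,
      nMissense = N, nNonsense = sum(v$kind == "nonsense"),
      meanScore = mean(mis$score),
      radicalFraction = mean(mis$radical),
      perDomain = pd)
})

#' @rdname accessors
setMethod("geneId", "ObservedCohort", function(x) x@geneId)

#' @rdname accessors
setMethod("variants", "ObservedCohort", function(x) x@variants)

setMethod("show", "ObservedCohort", function(object) {
  v <- object@variants
  cat(sprintf("ObservedCohort '%s': %d variant(s) (%d missense, %d nonsense) in %d case(s)\n",
              object@geneId, nrow(v), sum(v$kind == "missense"),
              sum(v$kind == "nonsense"), length(unique(v$case_id))))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary '%s': N = %d missense (+%d nonsense)\n",
              object@geneId, object@nMissense, object@nNonsense))
  cat(sprintf("  mean score %.3f, radical fraction %.3f\n",
              object@meanScore, object@radicalFraction))
  if (nrow(object@perDomain) > 1L) {
    cat("  per-domain:\n")
    print(object@perDomain, row.names = FALSE)
  }
})
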