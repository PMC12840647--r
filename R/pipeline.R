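#' Run the full selection-testing pipeline
#'
#' Composes the whole analysis for one gene: load the CDS, read and
#' validate the cohort, enumerate the neutral event set (over the observed
#' codons by default, or the whole CDS), summarize the cohort, draw Monte
#' Carlo replicates, compute the one-sided p-values, and — when a domain
#' map is given — the domain burden table and chi-square / G tests. Any
#' stage failure is re-raised with the stage name attached.
#'
#' @param config named list or path to a YAML file with entries:
#'   \describe{
#'     \item{gene_id}{gene identifier (required).}
#'     \item{cds_fasta}{path to the CDS FASTA (required).}
#'     \item{maf}{path to the MAF-lite cohort table (required).}
#'     \item{seed}{integer RNG seed (required for a reproducible run).}
#'     \item{weights}{preset name (`"uniform"`/`"titv"`) or path to a
#'       weights file; default `"uniform"`.}
#'     \item{domains}{optional path to a domain map file.}
#'     \item{protein_fasta}{optional protein FASTA cross-check.}
#'     \item{M}{replicate count; default 7600.}
#'     \item{whole_cds}{enumerate over all codons instead of the observed
#'       ones; default FALSE.}
#'     \item{radical_threshold}{inclusive radical cutoff; default 0.}
#'     \item{on_mismatch}{`"error"` or `"skip"`; default `"error"`.}
#'     \item{per_biospecimen}{keep duplicate (case, change) rows; default
#'       FALSE.}
#'     \item{correction}{p-value correction, `"none"` or `"add-one"`.}
#'     \item{out_dir}{optional output directory; when given, Table-style
#'       TSVs and a JSON run manifest are written.}
#'   }
#' @return invisibly, a list with elements `gene`, `cohort`, `summary`,
#'   `eventTable`, `neutral` (expected mean/radical fraction), `replicates`,
#'   `test`, `domainTable`, `gof`, `summaryRow` (the one-row Table-1-style
#'   data.frame) and `manifest`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- config
  for (req in c("gene_id", "cds_fasta", "maf", "seed"))
    if (is.null(cfg[[req]]))
      stop(sprintf("config is missing required entry '%s'", req))
  get <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  M <- as.integer(get("M", 7600L))
  seed <- as.integer(cfg$seed)
  thr <- get("radical_threshold", 0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  gene <- stage("load", loadCDS(cfg$cds_fasta, cfg$gene_id,
                                proteinFasta = cfg$protein_fasta))
  w <- stage("weights", {
    ws <- get("weights", "uniform")
    if (is(ws, "SubstitutionWeights")) ws
    else if (ws %in% c("uniform", "titv")) substitutionWeights(ws)
    else readSubstitutionWeights(ws)
  })
  variants <- stage("read", readMafLite(cfg$maf, cfg$gene_id,
                                        perBiospecimen = isTRUE(cfg$per_biospecimen)))
  message(sprintf("[read] %d variant row(s) for %s (%d unparseable skipped)",
                  nrow(variants), cfg$gene_id,
                  attr(variants, "n_skipped") %||% 0L))
  cohort <- stage("validate",
                  observedCohort(gene, variants,
                                 onMismatch = get("on_mismatch", "error"),
                                 radicalThreshold = thr))
  domains <- stage("domains", {
    if (is.null(cfg$domains)) NULL
    else if (is(cfg$domains, "DomainMap")) cfg$domains
    else readDomainMap(cfg$domains, cfg$gene_id)
  })
  summary <- stage("summarize", summarizeCohort(cohort, domains))
  message(sprintf("[summarize] N = %d missense, %d nonsense; mean %.3f, radical %.3f",
                  summary@nMissense, summary@nNonsense,
                  summary@meanScore, summary@radicalFraction))
  positions <- if (isTRUE(cfg$whole_cds)) seq_len(geneLength(gene)) else
    sort(unique(variants$position[variants$kind == "missense"]))
  tab <- stage("enumerate", enumerateEvents(gene, positions, w,
                                            radicalThreshold = thr))
  message(sprintf("[enumerate] %d events over %d codon(s)",
                  nrow(tab@events), length(tab@includedPositions)))
  neutral <- neutralSummary(tab)
  reps <- stage("simulate",
                simulateReplicates(tab, N = summary@nMissense, M = M,
                                   seed = seed))
  test <- stage("test", pValues(reps, summary@meanScore,
                                summary@radicalFraction,
                                correction = get("correction", "none")))

  domainTable <- NULL
  gof <- NULL
  if (!is.null(domains)) {
    domainTable <- stage("domains", buildDomainTable(tab, summary, domains))
    keep <- domainTable$neutral_frac > 0
    gof <- stage("gof", goodnessOfFit(domainTable$observed_count[keep],
                                      domainTable$neutral_frac[keep]))
  }

  summaryRow <- data.frame(
    gene = cfg$gene_id, N = summary@nMissense, M = M, seed = seed,
    mu_obs = summary@meanScore, r_obs = summary@radicalFraction,
    neutral_mu_mean = mean(reps@meanScores),
    neutral_mu_sd = stats::sd(reps@meanScores),
    neutral_r_mean = mean(reps@radicalFractions),
    neutral_r_sd = stats::sd(reps@radicalFractions),
    p_mean = test@pMean, p_rad = test@pRad,
    p_mean_opposite = test@pMeanOpposite,
    p_rad_opposite = test@pRadOpposite,
    stringsAsFactors = FALSE)

  manifest <- list(gene = cfg$gene_id, N = summary@nMissense, M = M,
                   seed = seed, n_events = nrow(tab@events),
                   whole_cds = isTRUE(cfg$whole_cds),
                   radical_threshold = thr,
                   weights = as.list(w@w),
                   weights_hash = .weightsHash(w),
                   package_version = as.character(
                     utils::packageVersion("codonNeutral")))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, file) utils::write.table(
      x, file.path(cfg$out_dir, file), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(summaryRow, "summary.tsv")
    if (!is.null(domainTable)) wt(domainTable, "domains.tsv")
    if (!is.null(gof))
      wt(data.frame(gene = cfg$gene_id, chi2 = gof@chi2, chi2_p = gof@chi2P,
                    G = gof@G, G_p = gof@GP, df = gof@df), "gof.tsv")
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(gene = gene, cohort = cohort, summary = summary,
                 eventTable = tab, neutral = neutral, replicates = reps,
                 test = test, domainTable = domainTable, gof = gof,
                 summaryRow = summaryRow, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic content hash of the weights (md5 of a canonical rendering)
.weightsHash <- function(w) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%s=%.17g", names(w@w), w@w), f)
  unname(tools::md5sum(f))
}
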