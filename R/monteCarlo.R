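#' Draw Monte Carlo neutral replicates
#'
#' Each replicate draws `N` events i.i.d. from the categorical neutral
#' event distribution and records the replicate's mean BLOSUM score and
#' radical fraction. `N` is matched to the observed cohort size so the
#' replicate summaries are directly comparable to the observed ones.
#'
#' @param table a [NeutralEventTable-class].
#' @param N events per replicate (observed cohort size), at least 1.
#' @param M number of replicates, at least 1.
#' @param seed integer RNG seed; `NULL` leaves the RNG state to the caller.
#' @return a [ReplicateSet-class].
#' @examples
#' gm <- GeneModel("ATGCGT", "demo")
#' tab <- enumerateEvents(gm, 1:2, substitutionWeights("uniform"))
#' reps <- simulateReplicates(tab, N = 10, M = 100, seed = 1)
#' @export
simulateReplicates <- function(table, N, M, seed = NULL) {
  stopifnot(is(table, "NeutralEventTable"))
  N <- as.integer(N); M <- as.integer(M)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  if (is.na(M) || M < 1L) stop("M must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ev <- table@events
  draws <- sample.int(nrow(ev), N * M, replace = TRUE, prob = ev$prob)
  s <- matrix(ev$score[draws], nrow = N, ncol = M)
  r <- matrix(ev$radical[draws], nrow = N, ncol = M)
  new("ReplicateSet", M = M, N = N,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      meanScores = colMeans(s), radicalFractions = colMeans(r))
}

#' One-sided empirical p-values against the neutral replicates
#'
#' The primary direction asks whether the observed cohort is more
#' evolutionarily radical than neutral expectation: `pMean` is the fraction
#' of replicates whose mean score is at or below the observed mean, `pRad`
#' the fraction whose radical fraction is at or above the observed one.
#' The opposite (conservative) tails are always reported as well, with
#' reversed non-strict inequalities; ties therefore count toward both
#' tails. With `correction = "add-one"` each tail uses `(1 + count) /
#' (M + 1)` and never reports exactly zero; the default is the plain
#' empirical fraction. Monte Carlo standard errors `sqrt(p (1 - p) / M)`
#' accompany every estimate.
#'
#' @param reps a [ReplicateSet-class].
#' @param muObs observed mean BLOSUM score.
#' @param rObs observed radical fraction.
#' @param correction `"none"` (plain fraction, default) or `"add-one"`.
#' @return a [NeutralTest-class].
#' @export
setMethod("pValues", "ReplicateSet",
          function(reps, muObs, rObs, correction = c("none", "add-one")) {
  correction <- match.arg(correction)
  M <- reps@M
  est <- function(count)
    if (correction == "add-one") (1 + count) / (M + 1) else count / M
  pMean <- est(sum(reps@meanScores <= muObs))
  pRad <- est(sum(reps@radicalFractions >= rObs))
  pMeanOpp <- est(sum(reps@meanScores >= muObs))
  pRadOpp <- est(sum(reps@radicalFractions <= rObs))
  p <- c(p_mean = pMean, p_rad = pRad,
         p_mean_opposite = pMeanOpp, p_rad_opposite = pRadOpp)
  new("NeutralTest", pMean = pMean, pRad = pRad,
      pMeanOpposite = pMeanOpp, pRadOpposite = pRadOpp,
      mcSe = sqrt(p * (1 - p) / M), M = M)
})

#' Monte Carlo convergence diagnostics
#'
#' Reruns the p-value estimates on nested prefixes of a single replicate
#' stream (so the grid shares draws, the standard nested design) and flags
#' non-convergence whenever two successive estimates differ by more than
#' three pooled Monte Carlo standard errors. The default grid ends at
#' M = 7600 replicates, where the estimates are expected to have settled
#' well below their sampling noise.
#'
#' @param table a [NeutralEventTable-class].
#' @param N events per replicate.
#' @param seed integer RNG seed.
#' @param mGrid increasing vector of replicate counts.
#' @param muObs,rObs observed statistics; when omitted only the null mean
#'   trajectory is reported.
#' @return data.frame with one row per grid point: `M`, running null means
#'   `mean_mu`/`mean_r`, and when observations are supplied `p_mean`,
#'   `p_rad`, their standard errors, and logical `flag_mean`/`flag_rad`
#'   marking jumps beyond 3 pooled SEs from the previous grid point.
#' @export
convergenceCheck <- function(table, N, seed,
                             mGrid = c(500L, 1000L, 2000L, 4000L, 7600L),
                             muObs = NULL, rObs = NULL) {
  mGrid <- as.integer(mGrid)
  if (is.unsorted(mGrid, strictly = TRUE))
    stop("mGrid must be strictly increasing")
  reps <- simulateReplicates(table, N, max(mGrid), seed)
  rows <- lapply(mGrid, function(m) {
    mu <- reps@meanScores[seq_len(m)]
    r <- reps@radicalFractions[seq_len(m)]
    out <- data.frame(M = m, mean_mu = mean(mu), mean_r = mean(r))
    if (!is.null(muObs) && !is.null(rObs)) {
      pm <- mean(mu <= muObs); pr <- mean(r >= rObs)
      out$p_mean <- pm
      out$p_rad <- pr
      out$se_mean <- sqrt(pm * (1 - pm) / m)
      out$se_rad <- sqrt(pr * (1 - pr) / m)
    }
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(muObs) && !is.null(rObs)) {
    k <- nrow(res)
    pooled <- function(se) sqrt(se[-k]^2 + se[-1L]^2)
    jump <- function(p, se) c(FALSE, abs(diff(p)) > 3 * pmax(pooled(se), 1e-12))
    if (k > 1L) {
      res$flag_mean <- jump(res$p_mean, res$se_mean)
      res$flag_rad <- jump(res$p_rad, res$se_rad)
    } else {
      res$flag_mean <- FALSE
      res$flag_rad <- FALSE
    }
  }
  res
}

#' @rdname accessors
setMethod("meanScores", "ReplicateSet", function(x) x@meanScores)

#' @rdname accessors
setMethod("radicalFractions", "ReplicateSet", function(x) x@radicalFractions)

setMethod("show", "ReplicateSet", function(object) {
  cat(sprintf("ReplicateSet: M = %d replicates of N = %d draws (seed %s)\n",
              object@M, object@N,
              if (is.na(object@seed)) "external" else object@seed))
  cat(sprintf("  mean score %.3f +/- %.3f, radical fraction %.3f +/- %.3f\n",
              mean(object@meanScores), stats::sd(object@meanScores),
              mean(object@radicalFractions),
              stats::sd(object@radicalFractions)))
})

setMethod("show", "NeutralTest", function(object) {
  cat(sprintf("NeutralTest (M = %d replicates)\n", object@M))
  cat(sprintf("  radical direction:      p_mean = %.4g, p_rad = %.4g\n",
              object@pMean, object@pRad))
  cat(sprintf("  conservative direction: p_mean = %.4g, p_rad = %.4g\n",
              object@pMeanOpposite, object@pRadOpposite))
})
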