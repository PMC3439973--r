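# reporting module: chain-averaged likelihood ratios, the consensus mapping
# matrix, interval projection, redundancy pruning, and the final call set.

#' Chain-averaged likelihood ratio of a variant
#'
#' Approximates the likelihood ratio over the space of mapping matrices by
#' the chain average `(1/N) sum_i Lambda(V, M_i)`. Computed exactly from
#' the sampled support-count occupancies, on the log scale.
#'
#' @param cs A [ChainSummary-class].
#' @param prob The `svProblem` the chain was run on.
#' @param j Candidate column index (or id in `prob$cols`).
#' @return `log Lambda(V)` (log of the chain-averaged ratio).
#' @export
chainLambda <- function(cs, prob, j) {
  if (is.character(j)) j <- match(j, prob$cols)
  hist <- cs@supportHist[j, ]
  N <- sum(hist)
  if (N == 0) {
    # variant never supported during the chain: empty-support evaluation
    return(prob$colLogLambda[j, 1])
  }
  k <- which(hist > 0) - 1
  logw <- log(hist[k + 1]) - log(N)
  logsumexp(logw + prob$colLogLambda[j, k + 1])
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0) return(-Inf)
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Consensus mapping matrix from chain marginals
#'
#' Assigns each movable fragment to the candidate whose chain marginal
#' satisfies `mbar_ij >= tau`; fragments without such a candidate are left
#' unassigned. With `tau >= 0.5` at most one candidate per fragment can
#' qualify (the threshold is inclusive at 0.5).
#'
#' @param cs A [ChainSummary-class].
#' @param tau Threshold in `[0.5, 1)`.
#' @return Named integer vector over movable fragments (0 = unassigned,
#'   else candidate column index).
#' @export
consensusMatrix <- function(cs, tau = 0.5) {
  if (tau < 0.5 || tau >= 1)
    stop("tau must lie in [0.5, 1): below 0.5 two cells per row could pass")
  m <- nrow(cs@mbar)
  n <- length(cs@cols)
  gamma <- integer(m)
  if (m > 0) {
    mb <- cs@mbar[, seq_len(n), drop = FALSE]
    for (i in seq_len(m)) {
      jmax <- which.max(mb[i, ])
      if (mb[i, jmax] >= tau) gamma[i] <- jmax
    }
  }
  setNames(gamma, cs@rows)
}

#' Project a breakend polygon onto the reference interval
#'
#' `[amax, bmin]` with `amax = max a` and `bmin = min b` over the polygon;
#' for non-deletion signatures the pair may be reversed, in which case the
#' ordered pair is returned with `reversed = TRUE`.
#'
#' @param poly A non-empty [BreakendPolygon-class].
#' @return List with `start`, `end`, `amax`, `bmin`, `reversed`.
#' @export
projectInterval <- function(poly) {
  if (isEmpty(poly)) stop("empty polygon has no interval")
  v <- poly@vertices
  amax <- max(v[, 1]); bmin <- min(v[, 2])
  list(start = min(amax, bmin), end = max(amax, bmin),
       amax = amax, bmin = bmin, reversed = amax > bmin)
}

#' Prune redundant calls
#'
#' Two calls are redundant when the intersection of their projected
#' intervals is at least 50% of their union, or when one interval contains
#' the other. Calls are processed greedily by descending score (ties broken
#' by interval coordinates); a call is kept iff it is not redundant with any
#' already-kept call.
#'
#' @param calls Data.frame with columns `chromA`, `start`, `end` and the
#'   score column named by `scoreKey`.
#' @param scoreKey Name of the score column (default `"logLambda"`).
#' @return The pruned data.frame (original row order by descending score).
#' @export
pruneCalls <- function(calls, scoreKey = "logLambda") {
  if (nrow(calls) <= 1) return(calls)
  ord <- order(-calls[[scoreKey]], calls$chromA, calls$start, calls$end)
  calls <- calls[ord, , drop = FALSE]
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ki <- which(keep & calls$chromA == calls$chromA[i])
    red <- FALSE
    for (j in ki) {
      if (intervalsRedundant(calls$start[i], calls$end[i],
                             calls$start[j], calls$end[j])) {
        red <- TRUE
        break
      }
    }
    keep[i] <- !red
  }
  calls[keep, , drop = FALSE]
}

intervalsRedundant <- function(s1, e1, s2, e2) {
  inter <- min(e1, e2) - max(s1, s2) + 1
  if (inter <= 0) return(FALSE)
  uni <- max(e1, e2) - min(s1, s2) + 1
  contain <- (s1 <= s2 && e2 <= e1) || (s2 <= s1 && e1 <= e2)
  contain || inter >= 0.5 * uni
}

#' Derive the final call set from chains
#'
#' Builds the consensus mapping matrix, recomputes each supported variant's
#' support count under it, rescores with the read-depth models, filters by
#' log likelihood ratio and minimum support, and prunes redundant calls.
#' When every fragment has a unique candidate (nothing movable) this reduces
#' exactly to direct scoring of the clusters.
#'
#' @param chains List of [ChainSummary-class] objects (one per connected
#'   component; may be empty when nothing was sampled).
#' @param probs List of matching `svProblem` objects.
#' @param cov A `CoverageIndex`.
#' @param params A [ModelParams-class].
#' @param mapTrack Optional mapability track.
#' @param tau Consensus threshold (default 0.5).
#' @param minLogLambda Reporting threshold on `log Lambda` (default 0,
#'   exclusive).
#' @param minSupport Minimum consensus support per call (default 1).
#' @param breakendOnly,homozygousOnly Model switches, see [scoreVariant()].
#' @return An [SVCalls-class].
#' @export
finalizeCalls <- function(chains, probs, cov, params, mapTrack = NULL,
                          tau = 0.5, minLogLambda = 0, minSupport = 1,
                          breakendOnly = FALSE, homozygousOnly = FALSE) {
  rows <- list()
  for (ci in seq_along(probs)) {
    prob <- probs[[ci]]
    cs <- if (ci <= length(chains)) chains[[ci]] else NULL
    n <- length(prob$cols)
    support <- prob$fixedSupport
    if (!is.null(cs) && nrow(cs@mbar) > 0) {
      gamma <- consensusMatrix(cs, tau)
      support <- support + tabulate(gamma[gamma > 0], nbins = n)
    }
    for (j in seq_len(n)) {
      if (support[j] < max(minSupport, 0)) next
      if (support[j] == 0 && minSupport > 0) next
      cand <- prob$cands[[j]]
      hyp <- prob$hyps[[j]]
      sc <- scoreFromHypotheses(hyp, support[j], params)
      if (homozygousOnly) {
        lp <- hypothesisLogProbs(hyp, support[j], params)
        sc$logLambda <- unname(lp["p2"] - lp["p0"])
        sc$chat <- if (lp["p2"] >= lp["p0"] && !hyp$capped) 2L else 0L
        sc$bestPair <- if (sc$chat == 2L) hyp$best2 else hyp$best0
      }
      lcl <- if (!is.null(cs) && nrow(cs@mbar) > 0)
        chainLambda(cs, prob, j)
      else
        prob$colLogLambda[j, support[j] + 1]
      pr <- projectInterval(cand$polygon)
      rows[[length(rows) + 1]] <- data.frame(
        id = cand$id, svtype = cand$svtype, signature = cand$signature,
        chromA = cand$chromA, chromB = cand$chromB,
        start = pr$start, end = pr$end,
        bestA = sc$bestPair[1], bestB = sc$bestPair[2],
        support = support[j], chat = sc$chat,
        logLambda = sc$logLambda, logChainLambda = lcl,
        capped = sc$capped, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else emptyCallFrame()
  calls <- calls[calls$logLambda > minLogLambda, , drop = FALSE]
  calls <- pruneCalls(calls)
  rownames(calls) <- NULL
  new("SVCalls", calls = calls, params = params)
}

emptyCallFrame <- function() {
  data.frame(id = character(0), svtype = character(0),
             signature = character(0), chromA = character(0),
             chromB = character(0), start = numeric(0), end = numeric(0),
             bestA = numeric(0), bestB = numeric(0), support = numeric(0),
             chat = integer(0), logLambda = numeric(0),
             logChainLambda = numeric(0), capped = logical(0),
             stringsAsFactors = FALSE)
}
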