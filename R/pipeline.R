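# End-to-end calling pipeline: classification -> geometric clustering ->
# per-component mapping-matrix sampling -> consensus scoring and pruning.

#' Call structural variants from classified fragments
#'
#' Runs the full pipeline: indexes concordant coverage, clusters discordant
#' fragments into candidate variants by trapezoid intersection, decomposes
#' the fragment-variant graph into connected components, samples mapping
#' matrices per component (components whose fragments all have a unique
#' candidate are resolved directly, without sampling), and derives the
#' final pruned call set.
#'
#' @param x An [SVFragments-class] (classified; see [pairReads()] and
#'   [filterAlignments()]).
#' @param params A [ModelParams-class].
#' @param mapTrack Optional mapability track (BED-graph-like data.frame).
#' @param hqOnly Skip the sampler and score clusters directly from the
#'   alignment matrix (every supporting fragment counted); with unique
#'   fragments this is identical to the sampled path.
#' @param burnin,nSamples Chain lengths per component.
#' @param seed Integer seed (mandatory unless no component needs sampling).
#' @param tau Consensus-matrix threshold.
#' @param minLogLambda,minSupport Reporting filters.
#' @param breakendOnly,homozygousOnly Model switches, see [scoreVariant()].
#' @param signatures Discordant signatures to cluster.
#' @param edgeCeiling Components with more fragment-candidate incidences
#'   than this are not sampled: only their unique-candidate fragments are
#'   assigned.
#' @param seqlengths Optional named chromosome lengths.
#' @return A list with `calls` ([SVCalls-class]), `candidates`
#'   ([SVCandidateSet-class]), `chains`, `problems`, and `coverage`.
#' @export
svCall <- function(x, params, mapTrack = NULL, hqOnly = FALSE,
                   burnin = 1e5, nSamples = 9e5, seed = 1L, tau = 0.5,
                   minLogLambda = 0, minSupport = 1, breakendOnly = FALSE,
                   homozygousOnly = FALSE,
                   signatures = c("deletion", "inversionPlus",
                                  "inversionMinus"),
                   edgeCeiling = 1e6, seqlengths = NULL) {
  stopifnot(is(x, "SVFragments"))
  cov <- coverageIndex(x, seqlengths = seqlengths)
  cands <- clusterDiscordants(x, signatures = signatures)
  if (length(cands) == 0) {
    return(list(calls = new("SVCalls", calls = emptyCallFrame(),
                            params = params),
                candidates = cands, chains = list(), problems = list(),
                coverage = cov))
  }
  comps <- connectedComponents(cands)
  probs <- vector("list", length(comps))
  chains <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    cc <- comps[[ci]]
    prob <- svSamplingProblem(candidates(cands)[cc$candIdx], cov, params,
                              mapTrack = mapTrack,
                              breakendOnly = breakendOnly,
                              homozygousOnly = homozygousOnly)
    probs[[ci]] <- prob
    edges <- sum(prob$A) + sum(prob$fixedSupport)
    if (!hqOnly && nrow(prob$A) > 0 && edges <= edgeCeiling) {
      chains[[ci]] <- runChain(prob, burnin = burnin, nSamples = nSamples,
                               seed = seed + ci)
    } else {
      chains[ci] <- list(NULL)  # resolved directly: fixed rows only
    }
  }
  calls <- finalizeCalls(chains, probs, cov, params, mapTrack = mapTrack,
                         tau = tau, minLogLambda = minLogLambda,
                         minSupport = minSupport,
                         breakendOnly = breakendOnly,
                         homozygousOnly = homozygousOnly)
  list(calls = calls, candidates = cands, chains = chains,
       problems = probs, coverage = cov)
}
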