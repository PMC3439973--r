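#' @import methods
#' @importFrom stats dpois qpois rnorm rpois runif quantile setNames
#' @importFrom utils head read.table write.table combn
NULL

#' Paired-end library statistics
#'
#' Holds the fragment-length bounds used to decide concordance, the average
#' fragment length used by the coverage models, the read length, and the
#' sequencing technology that fixes the convergent-orientation convention.
#'
#' @slot lmin,lmax Minimum and maximum concordant fragment length (bases).
#' @slot lavg Average fragment length (bases).
#' @slot readLength Read length (bases).
#' @slot technology Either `"illumina-convergent"` (convergent = +/- with the
#'   left read forward) or `"solid-same-strand"` (reads sequenced from the
#'   same strand).
#' @exportClass LibraryStats
setClass("LibraryStats",
  representation(
    lmin = "numeric", lmax = "numeric", lavg = "numeric",
    readLength = "numeric", technology = "character"
  ),
  prototype(technology = "illumina-convergent")
)

setValidity("LibraryStats", function(object) {
  msg <- character(0)
  if (length(object@lmin) != 1 || length(object@lmax) != 1 ||
      length(object@lavg) != 1) {
    msg <- c(msg, "lmin, lmax, lavg must be scalars")
  } else {
    if (!(object@lmin <= object@lavg && object@lavg <= object@lmax))
      msg <- c(msg, "must satisfy lmin <= lavg <= lmax")
  }
  if (object@readLength < 1) msg <- c(msg, "readLength must be >= 1")
  if (!object@technology %in% c("illumina-convergent", "solid-same-strand"))
    msg <- c(msg, "unknown technology")
  if (length(msg)) msg else TRUE
})

#' Construct LibraryStats
#'
#' @param lmin,lmax Concordant fragment-length bounds (bases).
#' @param lavg Average fragment length; defaults to the midpoint of
#'   `[lmin, lmax]`.
#' @param readLength Read length in bases.
#' @param technology Orientation convention, see [LibraryStats-class].
#' @return A [LibraryStats-class] object.
#' @examples
#' LibraryStats(100, 293, lavg = 200, readLength = 50)
#' @export
LibraryStats <- function(lmin, lmax, lavg = (lmin + lmax) / 2,
                         readLength = 50,
                         technology = c("illumina-convergent",
                                        "solid-same-strand")) {
  technology <- match.arg(technology)
  new("LibraryStats", lmin = as.numeric(lmin), lmax = as.numeric(lmax),
      lavg = as.numeric(lavg), readLength = as.numeric(readLength),
      technology = technology)
}

setMethod("show", "LibraryStats", function(object) {
  cat(sprintf(
    "LibraryStats: Lmin=%g Lmax=%g Lavg=%g readLength=%g (%s)\n",
    object@lmin, object@lmax, object@lavg, object@readLength,
    object@technology))
})

#' Fragment alignments with concordance classification
#'
#' Container for candidate fragment placements (one row per fragment
#' alignment: a choice of one alignment for each read of the pair), together
#' with the library statistics used to classify them. The breakpoint-proximal
#' coordinates `x < y` and their strand signs feed the breakend-polygon
#' geometry; `status`/`signature` record the concordance call. The
#' fragment-level column `fragClass` partitions fragments into
#' `concordant-unique`, `discordant` (every alignment discordant) and
#' `excluded`.
#'
#' @slot alignments A data.frame with one row per fragment alignment; columns
#'   `fragment`, `chromX`, `x`, `signX`, `chromY`, `y`, `signY`, `span`,
#'   `status`, `signature`, `mapq`, plus raw read coordinates
#'   (`pos1`, `strand1`, `len1`, `pos2`, `strand2`, `len2`).
#' @slot stats The [LibraryStats-class] used for classification.
#' @slot fragClass Named character vector: per-fragment partition class.
#' @exportClass SVFragments
setClass("SVFragments",
  representation(alignments = "data.frame", stats = "LibraryStats",
                 fragClass = "character"))

setValidity("SVFragments", function(object) {
  al <- object@alignments
  need <- c("fragment", "chromX", "x", "signX", "chromY", "y", "signY",
            "span", "status", "signature")
  if (!all(need %in% names(al)))
    return(paste("alignments missing columns:",
                 paste(setdiff(need, names(al)), collapse = ", ")))
  same <- al$chromX == al$chromY
  if (any(same & al$x >= al$y))
    return("x < y violated for same-chromosome alignments")
  if (!all(al$signX %in% c(-1, 1)) || !all(al$signY %in% c(-1, 1)))
    return("signs must be +1/-1")
  TRUE
})

setMethod("show", "SVFragments", function(object) {
  al <- object@alignments
  cat(sprintf("SVFragments: %d alignments of %d fragments\n",
              nrow(al), length(unique(al$fragment))))
  if (length(object@fragClass)) {
    tb <- table(object@fragClass)
    cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "), "\n")
  }
  show(object@stats)
})

#' Model parameters for the Poisson read-depth likelihoods
#'
#' @slot lambda Fragments per base (Poisson process rate of fragment left
#'   ends over the whole genome).
#' @slot lavg,readLength Library properties used for the derived means.
#' @slot pErr Per-fragment erroneous-mapping probability.
#' @slot eta Rate of the exponential prior on the number of variants.
#' @slot alphaMap,betaMap Mapability scaling weights (must sum to 1).
#' @slot capQuantile Poisson quantile above which concordant coverage forces
#'   the no-variant copy call.
#' @exportClass ModelParams
setClass("ModelParams",
  representation(lambda = "numeric", lavg = "numeric", readLength = "numeric",
                 pErr = "numeric", eta = "numeric", alphaMap = "numeric",
                 betaMap = "numeric", capQuantile = "numeric"))

setValidity("ModelParams", function(object) {
  msg <- character(0)
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@pErr <= 0 || object@pErr >= 1)
    msg <- c(msg, "pErr must be in (0,1)")
  if (object@lavg <= 2 * object@readLength)
    msg <- c(msg, "lavg must exceed 2*readLength (else lambda_d < 0)")
  if (abs(object@alphaMap + object@betaMap - 1) > 1e-12)
    msg <- c(msg, "alphaMap + betaMap must equal 1")
  if (object@eta <= 0) msg <- c(msg, "eta must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct ModelParams
#'
#' @param lambda Fragment rate per base.
#' @param lavg Average fragment length (bases).
#' @param readLength Read length (bases).
#' @param pErr Erroneous-mapping probability per fragment.
#' @param eta Exponential prior rate on the variant count.
#' @param alphaMap,betaMap Mapability scaling weights.
#' @param capQuantile Coverage-cap quantile.
#' @return A [ModelParams-class] object.
#' @examples
#' p <- ModelParams(lambda = 0.3, lavg = 200, readLength = 50)
#' lambdaC(p)  # 60
#' lambdaD(p)  # 30
#' @export
ModelParams <- function(lambda, lavg = 200, readLength = 50, pErr = 0.01,
                        eta = 1e-3, alphaMap = 0.3, betaMap = 0.7,
                        capQuantile = 0.9999) {
  new("ModelParams", lambda = lambda, lavg = lavg, readLength = readLength,
      pErr = pErr, eta = eta, alphaMap = alphaMap, betaMap = betaMap,
      capQuantile = capQuantile)
}

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(
    paste0("ModelParams: lambda=%g (lambda_c=%g, lambda_d=%g) pErr=%g ",
           "eta=%g alpha=%g beta=%g cap=%g\n"),
    object@lambda, lambdaC(object), lambdaD(object), object@pErr,
    object@eta, object@alphaMap, object@betaMap, object@capQuantile))
})

#' Convex breakend polygon
#'
#' The convex region of mated breakend pairs (a, b) consistent with one or
#' more discordant fragment alignments: the band
#' `Lmin <= sign(x)(a-x) + sign(y)(b-y) <= Lmax` for every supporting
#' fragment, intersected with the signature's bounding box. Represented both
#' as half-planes (`A*a + B*b <= C`, integer coefficients) and as an ordered
#' vertex list; an empty polygon has zero vertices.
#'
#' @slot halfplanes Numeric matrix with columns `A`, `B`, `C`.
#' @slot vertices Two-column numeric matrix of (a, b) vertices in
#'   counter-clockwise order (0 rows when empty; 1 or 2 rows for degenerate
#'   point/segment polygons).
#' @slot signature Discordant signature (`"deletion"`, `"inversionPlus"`,
#'   `"inversionMinus"`, `"divergent"`, `"translocation"`).
#' @slot chromA,chromB Chromosomes of the left and right breakend axes.
#' @exportClass BreakendPolygon
setClass("BreakendPolygon",
  representation(halfplanes = "matrix", vertices = "matrix",
                 signature = "character", chromA = "character",
                 chromB = "character"))

setValidity("BreakendPolygon", function(object) {
  if (ncol(object@halfplanes) != 3) return("halfplanes must have 3 columns")
  if (nrow(object@vertices) > 0 && ncol(object@vertices) != 2)
    return("vertices must have 2 columns")
  TRUE
})

setMethod("show", "BreakendPolygon", function(object) {
  if (isEmpty(object)) {
    cat(sprintf("BreakendPolygon: empty (%s)\n", object@signature))
  } else {
    v <- object@vertices
    cat(sprintf(
      "BreakendPolygon (%s) %s:%s, %d vertices, a in [%g, %g], b in [%g, %g]\n",
      object@signature, object@chromA, object@chromB, nrow(v),
      min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2])))
  }
})

#' Candidate structural variants from geometric clustering
#'
#' Each candidate is a pair (F, B): the supporting discordant fragment set
#' and the breakend polygon equal to the intersection of the supporters'
#' trapezoids.
#'
#' @slot candidates List of candidate records; each has elements `id`,
#'   `fragments` (character vector), `polygon` ([BreakendPolygon-class]),
#'   `signature`, `chromA`, `chromB`, `k`, `amax`, `bmin`, `svtype`.
#' @exportClass SVCandidateSet
setClass("SVCandidateSet", representation(candidates = "list"))

setMethod("show", "SVCandidateSet", function(object) {
  k <- vapply(object@candidates, function(cc) cc$k, numeric(1))
  sg <- vapply(object@candidates, function(cc) cc$signature, character(1))
  cat(sprintf("SVCandidateSet: %d candidates\n", length(object@candidates)))
  if (length(k)) {
    tb <- table(sg)
    cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "),
        sprintf("  support: median %g, max %g\n", stats::median(k), max(k)))
  }
})

setMethod("length", "SVCandidateSet", function(x) length(x@candidates))

#' Summary of a Metropolis-Hastings run over mapping matrices
#'
#' @slot mbar Matrix (movable fragments x candidates) of chain marginal
#'   assignment probabilities; an extra last column holds the unassigned
#'   (mapping-error) marginal.
#' @slot supportHist Matrix (candidates x support levels 0..kmax) of sampled
#'   total-support occupancy counts.
#' @slot stateCounts Optional named numeric of visit counts per encoded
#'   mapping-matrix state (small instances only), else length 0.
#' @slot acceptRates Per-move-class proposal and acceptance counts.
#' @slot nSamples Number of post-burn-in samples.
#' @slot seed Integer seed used.
#' @slot rows,cols Fragment and candidate identifiers.
#' @slot fixedAssign Named integer: column index for rows fixed outside the
#'   sampler (unique-assignment heuristic).
#' @exportClass ChainSummary
setClass("ChainSummary",
  representation(mbar = "matrix", supportHist = "matrix",
                 stateCounts = "numeric", acceptRates = "matrix",
                 nSamples = "numeric", seed = "integer",
                 rows = "character", cols = "character",
                 fixedAssign = "integer"))

setValidity("ChainSummary", function(object) {
  if (nrow(object@mbar) > 0) {
    if (any(object@mbar < -1e-9 | object@mbar > 1 + 1e-9))
      return("mbar entries must lie in [0,1]")
    rs <- rowSums(object@mbar)
    if (any(rs > 1 + 1e-6)) return("mbar row sums must be <= 1")
  }
  TRUE
})

setMethod("show", "ChainSummary", function(object) {
  cat(sprintf(
    "ChainSummary: %d movable fragments x %d candidates, %g samples (seed %d)\n",
    nrow(object@mbar), length(object@cols), object@nSamples, object@seed))
  if (nrow(object@acceptRates) > 0) {
    ar <- object@acceptRates
    ok <- ar[, "proposed"] > 0
    if (any(ok)) {
      cat("  acceptance: ",
          paste(sprintf("%s=%.2f", rownames(ar)[ok],
                        ar[ok, "accepted"] / ar[ok, "proposed"]),
                collapse = "  "), "\n")
    }
  }
})

#' Final structural-variant call set
#'
#' @slot calls Data.frame of final calls (one row per reported variant).
#' @slot params The [ModelParams-class] used for scoring.
#' @exportClass SVCalls
setClass("SVCalls",
  representation(calls = "data.frame", params = "ModelParams"))

setMethod("show", "SVCalls", function(object) {
  cat(sprintf("SVCalls: %d calls\n", nrow(object@calls)))
  if (nrow(object@calls)) {
    tb <- table(object@calls$svtype)
    cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "), "\n")
    print(head(object@calls, 5))
  }
})

setMethod("length", "SVCalls", function(x) nrow(x@calls))
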