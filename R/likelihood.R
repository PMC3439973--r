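# likelihood module: Poisson log-pmf with continuous extension, the
# copy-number-conditional probabilities of the generic breakend model, the
# deletion interval model, mapability scaling, and the coverage cap.

#' Poisson log-probability with continuous count extension
#'
#' Computes `log(mean^k exp(-mean) / k!)` via the gamma-function extension
#' `lgamma(k+1)` of `log k!`, so non-integer counts (arising from mapability
#' scaling of observed fragment counts) are handled without a rounding
#' discontinuity. Conventions: `Pois(0; 0) = 1` and `Pois(0; k>0) = 0`.
#'
#' @param mean Poisson mean (>= 0).
#' @param k Count (>= 0, not necessarily integer). Vectorized with `mean`.
#' @return Log probability (possibly `-Inf`).
#' @examples
#' poissonLogPmf(2, 2)  # log(2 exp(-2)) ~ -1.3069
#' @export
poissonLogPmf <- function(mean, k) {
  if (any(mean < 0)) stop("mean must be >= 0")
  if (any(k < 0)) stop("k must be >= 0")
  n <- max(length(mean), length(k))
  mean <- rep_len(mean, n); k <- rep_len(k, n)
  out <- numeric(n)
  z <- mean == 0
  out[z] <- ifelse(k[z] == 0, 0, -Inf)
  nz <- !z
  out[nz] <- k[nz] * log(mean[nz]) - mean[nz] - lgamma(k[nz] + 1)
  out
}

#' Copy-number-conditional log-probability of a generic breakend variant
#'
#' For a candidate variant with `k` supporting discordant fragments and
#' breakend coverages `nA = n(a)`, `nB = n(b)`:
#' homozygous (`c = 2`): `(nA+nB) log pErr + logPois(lambda_d; k)`;
#' heterozygous (`c = 1`):
#' `logPois(lambda_c/2; nA) + logPois(lambda_c/2; nB) + logPois(lambda_d/2; k)`;
#' no variant (`c = 0`):
#' `logPois(lambda_c; nA) + logPois(lambda_c; nB) + k log pErr`.
#'
#' @param c Copy count of the novel adjacency: 0, 1 or 2.
#' @param k Number of supporting discordant fragments.
#' @param nA,nB Concordant coverage at the two breakends.
#' @param params A [ModelParams-class].
#' @return Log probability.
#' @export
copyConditionalLogProb <- function(c, k, nA, nB, params) {
  stopifnot(c %in% 0:2, k >= 0, nA >= 0, nB >= 0)
  lc <- lambdaC(params); ld <- lambdaD(params); lpe <- log(params@pErr)
  if (c == 2) {
    (nA + nB) * lpe + poissonLogPmf(ld, k)
  } else if (c == 1) {
    poissonLogPmf(lc / 2, nA) + poissonLogPmf(lc / 2, nB) +
      poissonLogPmf(ld / 2, k)
  } else {
    poissonLogPmf(lc, nA) + poissonLogPmf(lc, nB) + k * lpe
  }
}

#' Mapability scaling of a concordant fragment count
#'
#' `n_hat = n / (alpha + beta * R)` where `R` is the fraction of uniquely
#' mapable bases in the queried interval. With `R = 1` the count is
#' unchanged.
#'
#' @param n Observed concordant count (>= 0).
#' @param R Mapability fraction in `[0, 1]`.
#' @param params A [ModelParams-class] (uses `alphaMap`, `betaMap`).
#' @return Scaled (possibly non-integer) count.
#' @examples
#' p <- ModelParams(0.3)
#' scaleConcordantCount(3, 0, p)   # 10
#' scaleConcordantCount(30, 0.5, p)
#' @export
scaleConcordantCount <- function(n, R, params) {
  if (any(R < 0 | R > 1)) stop("mapability R must lie in [0, 1]")
  stopifnot(all(n >= 0))
  n / (params@alphaMap + params@betaMap * R)
}

#' Extreme-coverage cap
#'
#' TRUE when the observed concordant count lies above the `capQuantile`
#' Poisson quantile of its reference mean, in which case the scorer forces
#' the no-variant copy call without evaluating alternatives.
#'
#' @param n Observed count.
#' @param mean Reference Poisson mean (> 0): the point-coverage mean for
#'   breakend counts, the interval mean for deletion interval counts.
#' @param capQuantile Quantile level (default 0.9999, i.e. the top 0.01%).
#' @return Logical.
#' @export
coverageCap <- function(n, mean, capQuantile = 0.9999) {
  stopifnot(mean > 0)
  n > qpois(capQuantile, mean)
}

#' Candidate breakend pairs covering every coverage cell of a polygon
#'
#' Returns a finite set of integer breakend pairs (a, b) guaranteed to
#' contain a maximizer of every copy-number-conditional probability over the
#' polygon: one representative per cell of the rectangular partition induced
#' by the coverage change-points of `n(a)` and `n(b)`, intersected with the
#' polygon. Representatives carry their coverages `nA`, `nB`.
#'
#' @param poly A non-empty [BreakendPolygon-class].
#' @param cov A `CoverageIndex` from [coverageIndex()].
#' @return Data.frame with columns `a`, `b`, `nA`, `nB`.
#' @export
candidateBreakendPairs <- function(poly, cov) {
  if (isEmpty(poly)) stop("empty breakend polygon")
  v <- poly@vertices
  aLo <- ceiling(min(v[, 1]) - GEOM_TOL); aHi <- floor(max(v[, 1]) + GEOM_TOL)
  bLo <- ceiling(min(v[, 2]) - GEOM_TOL); bHi <- floor(max(v[, 2]) + GEOM_TOL)
  if (aLo > aHi || bLo > bHi) {
    return(data.frame(a = numeric(0), b = numeric(0), nA = numeric(0),
                      nB = numeric(0)))
  }
  hp <- poly@halfplanes
  diag <- hp[hp[, 1] != 0 & hp[, 2] != 0, , drop = FALSE]
  # after normalization the band is one pair of opposite diagonal
  # constraints: s1*a + s2*b <= hi and -(s1*a + s2*b) <= -lo
  i <- which(diag[, 1] %in% c(1, -1))[1]
  s1 <- diag[i, 1]; s2 <- diag[i, 2]
  hi <- min(diag[diag[, 1] == s1 & diag[, 2] == s2, 3])
  lo <- -min(diag[diag[, 1] == -s1 & diag[, 2] == -s2, 3])

  cpA <- coverageChangePoints(cov, poly@chromA, aLo, aHi)
  cpB <- coverageChangePoints(cov, poly@chromB, bLo, bHi)
  nAvals <- concordantCoverage(cov, poly@chromA, at = cpA)
  nBvals <- concordantCoverage(cov, poly@chromB, at = cpB)
  A1 <- cpA; A2 <- c(cpA[-1] - 1, aHi)
  B1 <- cpB; B2 <- c(cpB[-1] - 1, bHi)

  # all (a-cell, b-cell) pairs, vectorized; within a cell both coverages are
  # constant, so one integer representative inside the band suffices. For
  # fixed a the band's b-window is [bl(a), bu(a)] with
  # bl(a) = iBL + slope*a, bu(a) = iBU + slope*a, slope = -s1*s2 in {-1,+1};
  # the window slides monotonically, so feasibility in a cell reduces to
  # one-sided integer bounds on a.
  na <- length(A1); nb <- length(B1)
  ia <- rep(seq_len(na), times = nb); ib <- rep(seq_len(nb), each = na)
  a1 <- A1[ia]; a2 <- A2[ia]; b1 <- B1[ib]; b2 <- B2[ib]
  slope <- -s1 * s2
  iBL <- if (s2 == 1) lo else -hi
  iBU <- if (s2 == 1) hi else -lo
  if (slope == 1) {
    aLoC <- pmax(a1, b1 - iBU)   # bu(a) >= B1
    aHiC <- pmin(a2, b2 - iBL)   # bl(a) <= B2
  } else {
    aLoC <- pmax(a1, iBL - b2)   # bl(a) <= B2
    aHiC <- pmin(a2, iBU - b1)   # bu(a) >= B1
  }
  ok <- aLoC <= aHiC
  if (!any(ok)) {
    return(data.frame(a = numeric(0), b = numeric(0), nA = numeric(0),
                      nB = numeric(0)))
  }
  a <- aLoC[ok]
  b <- pmax(b1[ok], iBL + slope * a)
  data.frame(a = a, b = b, nA = nAvals[ia[ok]], nB = nBvals[ib[ok]])
}

# Per-hypothesis coverage constants of the generic breakend model, maximized
# over the candidate breakend pairs. The (a,b)-dependent factor separates
# from the k-dependent factor within each hypothesis, so these are computed
# once per candidate variant.
breakendHypotheses <- function(poly, cov, params) {
  cells <- candidateBreakendPairs(poly, cov)
  if (nrow(cells) == 0) {
    # polygon thinner than one lattice cell: fall back to nearest lattice
    # point of the first vertex
    v <- poly@vertices[1, ]
    a <- round(v[1]); b <- round(v[2])
    cells <- data.frame(a = a, b = b,
                        nA = concordantCoverage(cov, poly@chromA, at = a),
                        nB = concordantCoverage(cov, poly@chromB, at = b))
  }
  lc <- lambdaC(params); lpe <- log(params@pErr)
  s2 <- cells$nA + cells$nB
  i2 <- which.min(s2)
  g1 <- poissonLogPmf(lc / 2, cells$nA) + poissonLogPmf(lc / 2, cells$nB)
  i1 <- which.max(g1)
  g0 <- poissonLogPmf(lc, cells$nA) + poissonLogPmf(lc, cells$nB)
  i0 <- which.max(g0)
  thr <- qpois(params@capQuantile, lc)
  capped <- min(pmax(cells$nA, cells$nB)) > thr
  list(
    model = "breakend",
    const2 = s2[i2] * lpe, const1 = g1[i1], const0 = g0[i0],
    best2 = c(cells$a[i2], cells$b[i2]),
    best1 = c(cells$a[i1], cells$b[i1]),
    best0 = c(cells$a[i0], cells$b[i0]),
    capped = capped
  )
}

# Hypothesis constants of the deletion interval model: coverage across
# I(B) = [amax, bmin], mapability-scaled.
deletionHypotheses <- function(poly, cov, params, mapTrack = NULL) {
  v <- poly@vertices
  amax <- floor(max(v[, 1]) + GEOM_TOL)
  bmin <- ceiling(min(v[, 2]) - GEOM_TOL)
  if (amax > bmin) return(NULL)  # caller falls back to the breakend model
  lamI <- params@lambda * (bmin - amax + params@lavg)
  nI <- concordantCoverage(cov, poly@chromA, from = amax, to = bmin)
  R <- mapabilityFraction(mapTrack, poly@chromA, amax, bmin)
  nHat <- scaleConcordantCount(nI, R, params)
  lpe <- log(params@pErr)
  thr <- qpois(params@capQuantile, lamI)
  list(
    model = "deletion",
    const2 = nHat * lpe,
    const1 = poissonLogPmf(lamI / 2, nHat),
    const0 = poissonLogPmf(lamI, nHat),
    best2 = c(amax, bmin), best1 = c(amax, bmin), best0 = c(amax, bmin),
    capped = nHat > thr,
    nI = nI, nHat = nHat, lambdaI = lamI, R = R
  )
}

# k-dependent completion of the hypothesis log-probabilities
hypothesisLogProbs <- function(hyp, k, params) {
  ld <- lambdaD(params)
  c(p0 = hyp$const0 + k * log(params@pErr),
    p1 = hyp$const1 + poissonLogPmf(ld / 2, k),
    p2 = hyp$const2 + poissonLogPmf(ld, k))
}

scoreFromHypotheses <- function(hyp, k, params) {
  lp <- hypothesisLogProbs(hyp, k, params)
  logLambda <- max(lp["p2"], lp["p1"]) - lp["p0"]
  chat <- c(0L, 1L, 2L)[which.max(lp)]
  if (hyp$capped) chat <- 0L
  bestPair <- switch(as.character(chat),
                     "2" = hyp$best2, "1" = hyp$best1, hyp$best0)
  list(logLambda = unname(logLambda), chat = chat, bestPair = bestPair,
       logP = unname(lp), capped = hyp$capped, model = hyp$model)
}

#' Score a candidate variant with the generic breakend model
#'
#' For each copy hypothesis the probability is maximized over the candidate
#' breakend pairs of the polygon; the returned log likelihood ratio is
#' `max(logP(c=2), logP(c=1)) - logP(c=0)`. When the extreme-coverage cap
#' fires the copy call is forced to 0.
#'
#' @param cand A candidate record from [clusterDiscordants()] (or any list
#'   with elements `polygon` and `k`).
#' @param cov A `CoverageIndex`.
#' @param params A [ModelParams-class].
#' @param k Support count override (defaults to `cand$k`).
#' @return List with `logLambda`, `chat`, `bestPair`, `logP`, `capped`.
#' @export
scoreBreakendVariant <- function(cand, cov, params, k = cand$k) {
  stopifnot(k >= 0)
  hyp <- breakendHypotheses(cand$polygon, cov, params)
  scoreFromHypotheses(hyp, k, params)
}

#' Score a deletion candidate with the interval read-depth model
#'
#' Uses the mapability-scaled concordant count over the necessarily deleted
#' interval `I(B) = [amax, bmin]` with Poisson mean
#' `lambda_I = lambda (bmin - amax + Lavg)`. Falls back to the generic
#' breakend model (with a message) when the polygon has `amax > bmin`.
#'
#' @inheritParams scoreBreakendVariant
#' @param mapTrack Optional mapability track (see [mapabilityFraction()]).
#' @return As [scoreBreakendVariant()], plus `nI`, `nHat`, `lambdaI`, `R`
#'   when the interval model applied.
#' @export
scoreDeletionVariant <- function(cand, cov, params, mapTrack = NULL,
                                 k = cand$k) {
  stopifnot(k >= 0)
  hyp <- deletionHypotheses(cand$polygon, cov, params, mapTrack)
  if (is.null(hyp)) {
    message("candidate ", cand$id %||% "", " has amax > bmin; ",
            "using the generic breakend model")
    return(scoreBreakendVariant(cand, cov, params, k = k))
  }
  out <- scoreFromHypotheses(hyp, k, params)
  out$nI <- hyp$nI; out$nHat <- hyp$nHat
  out$lambdaI <- hyp$lambdaI; out$R <- hyp$R
  out
}

#' Score a candidate with the model matching its signature
#'
#' Deletion-signature candidates use the interval model; inversion and
#' translocation signatures use the generic breakend model. Set
#' `breakendOnly = TRUE` to force the generic model everywhere.
#'
#' @inheritParams scoreDeletionVariant
#' @param breakendOnly Force the generic breakend model for all signatures.
#' @param homozygousOnly Restrict the variant hypotheses to `c = 2`
#'   (homozygous-only mode; the heterozygous hypothesis is dropped from the
#'   likelihood ratio and from the copy call).
#' @return As [scoreBreakendVariant()].
#' @export
scoreVariant <- function(cand, cov, params, mapTrack = NULL,
                         breakendOnly = FALSE, homozygousOnly = FALSE,
                         k = cand$k) {
  hyp <- variantHypotheses(cand, cov, params, mapTrack, breakendOnly)
  out <- scoreFromHypotheses(hyp, k, params)
  if (homozygousOnly) {
    lp <- hypothesisLogProbs(hyp, k, params)
    out$logLambda <- unname(lp["p2"] - lp["p0"])
    out$chat <- if (lp["p2"] >= lp["p0"] && !hyp$capped) 2L else 0L
    out$bestPair <- if (out$chat == 2L) hyp$best2 else hyp$best0
  }
  out
}

variantHypotheses <- function(cand, cov, params, mapTrack = NULL,
                              breakendOnly = FALSE) {
  if (!breakendOnly && cand$signature == "deletion") {
    hyp <- deletionHypotheses(cand$polygon, cov, params, mapTrack)
    if (!is.null(hyp)) return(hyp)
  }
  breakendHypotheses(cand$polygon, cov, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mapability fraction of an interval
#'
#' Mean per-base uniqueness value over `[from, to]` from a BED-graph-like
#' track (data.frame with `chrom`, `start`, `end`, `value`; 1-based closed
#' intervals). Bases not covered by the track count as fully mapable
#' (value 1). A `NULL` track gives R = 1 everywhere.
#'
#' @param track Mapability track data.frame or `NULL`.
#' @param chrom,from,to Query interval.
#' @return Scalar fraction in `[0, 1]`.
#' @export
mapabilityFraction <- function(track, chrom, from, to) {
  if (is.null(track)) return(1)
  stopifnot(from <= to)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0) return(1)
  s <- pmax(tr$start, from); e <- pmin(tr$end, to)
  w <- pmax(0, e - s + 1)
  len <- to - from + 1
  covered <- sum(w)
  (sum(w * tr$value) + (len - covered) * 1) / len
}
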