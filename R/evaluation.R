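# evaluation module: double-uncertainty matching of predictions against
# known variants and sensitivity / novel-prediction tables.

#' Double-uncertainty overlap between a prediction and a known variant
#'
#' A prediction with breakends (x, y) and uncertainty `eps` matches a known
#' variant with breakends (a, b) and uncertainty `delta` iff both closed
#' intervals intersect: `[x-eps, x+eps] n [a-delta, a+delta] != {}` and the
#' right-breakend counterpart. Touching intervals count as overlapping.
#'
#' @param x,y Predicted left/right breakends (vectors recycle).
#' @param a,b Known left/right breakends.
#' @param eps Prediction uncertainty in bases (default `Lmax/2` is the
#'   conventional choice; supply explicitly).
#' @param delta Reference uncertainty in bases (0 for breakpoint-exact truth
#'   sets; 200 is a conventional value for paired-read-derived truth sets).
#' @return Logical vector.
#' @export
duOverlap <- function(x, y, a, b, eps = 0, delta = 0) {
  stopifnot(all(eps >= 0), all(delta >= 0))
  abs(x - a) <= eps + delta & abs(y - b) <= eps + delta
}

#' Sensitivity / novel-prediction table over score thresholds
#'
#' For each threshold on the call score: the number of truth variants
#' matched by at least one call at or above the threshold (each truth
#' variant counted once), and the number of calls matching no truth variant
#' ("novel predictions").
#'
#' @param calls Data.frame with columns `chromA`, `bestA`, `bestB` (or
#'   `start`/`end` fallback) and a score column.
#' @param truth Data.frame with columns `chrom`, `a`, `b` and optionally a
#'   per-variant `delta`.
#' @param eps Prediction uncertainty (bases).
#' @param delta Default reference uncertainty (overridden by a `delta`
#'   column in `truth`).
#' @param scoreKey Score column name (default `"logLambda"`).
#' @return Data.frame with columns `threshold`, `nCalls`, `tp`, `novel`.
#' @export
rocTable <- function(calls, truth, eps, delta = 0,
                     scoreKey = "logLambda") {
  if (nrow(truth) == 0)
    warning("empty truth set: every call is a novel prediction")
  m <- duMatchMatrix(calls, truth, eps, delta)
  score <- calls[[scoreKey]]
  thresholds <- sort(unique(score), decreasing = TRUE)
  out <- lapply(thresholds, function(t) {
    use <- score >= t
    tp <- if (nrow(truth)) sum(colSums(m[use, , drop = FALSE]) > 0) else 0L
    novel <- sum(use & rowSums(m) == 0)
    data.frame(threshold = t, nCalls = sum(use), tp = tp, novel = novel)
  })
  do.call(rbind, out)
}

# calls x truth logical match matrix under the double-uncertainty metric
duMatchMatrix <- function(calls, truth, eps, delta = 0) {
  nx <- nrow(calls); nt <- nrow(truth)
  m <- matrix(FALSE, nx, nt)
  if (nx == 0 || nt == 0) return(m)
  px <- if ("bestA" %in% names(calls)) calls$bestA else calls$start
  py <- if ("bestB" %in% names(calls)) calls$bestB else calls$end
  dlt <- if ("delta" %in% names(truth)) truth$delta else rep(delta, nt)
  for (t in seq_len(nt)) {
    sameChrom <- calls$chromA == truth$chrom[t]
    m[, t] <- sameChrom &
      duOverlap(px, py, truth$a[t], truth$b[t], eps = eps, delta = dlt[t])
  }
  m
}

#' Compare a call set against a truth set at one threshold
#'
#' Convenience wrapper: sensitivity (fraction of truth variants matched) and
#' the false-call fraction (calls matching no truth variant).
#'
#' @inheritParams rocTable
#' @return List with `tp`, `sensitivity`, `novel`, `falseRate`, `nCalls`.
#' @export
evaluateCalls <- function(calls, truth, eps, delta = 0) {
  m <- duMatchMatrix(calls, truth, eps, delta)
  tp <- sum(colSums(m) > 0)
  novel <- sum(rowSums(m) == 0)
  list(tp = tp,
       sensitivity = if (nrow(truth)) tp / nrow(truth) else NA_real_,
       novel = novel,
       falseRate = if (nrow(calls)) novel / nrow(calls) else 0,
       nCalls = nrow(calls))
}
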