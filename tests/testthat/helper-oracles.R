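# Shared independent oracles and fixture builders. Oracles are written
# directly from the model definitions and never call the code paths they
# check.

# default library for unit fixtures
testStats <- function(lmin = 100, lmax = 200, lavg = 150, rl = 50) {
  LibraryStats(lmin, lmax, lavg, readLength = rl)
}

# direct inequality membership check for a single-fragment trapezoid:
# Lmin <= sx(a-x) + sy(b-y) <= Lmax plus the proximal-side box
latticeMember <- function(a, b, x, y, sx, sy, lmin, lmax) {
  s <- sx * (a - x) + sy * (b - y)
  s >= lmin & s <= lmax &
    (if (sx == 1) a >= x else a <= x) &
    (if (sy == 1) b >= y else b <= y)
}

# O(n*m) coverage scan
bruteCoverage <- function(starts, ends, at) {
  vapply(at, function(p) sum(starts <= p & ends >= p), numeric(1))
}
bruteIntervalCoverage <- function(starts, ends, from, to) {
  sum(starts <= to & ends >= from)
}

# minimal union-find for the bipartite component oracle
unionFindComponents <- function(nNodes, edges) {
  parent <- seq_len(nNodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(nNodes), find, numeric(1))
}

# total variation between a named empirical distribution and exact
# probabilities keyed the same way
tvDistance <- function(emp, exact) {
  allk <- union(names(emp), names(exact))
  e1 <- ifelse(is.na(emp[allk]), 0, emp[allk])
  e2 <- ifelse(is.na(exact[allk]), 0, exact[allk])
  0.5 * sum(abs(e1 - e2))
}

exactKeyed <- function(prob) {
  ex <- exactMappingDistribution(prob)
  setNames(ex$prob, apply(ex$states, 1, paste, collapse = ","))
}

# read-level table for one fragment alignment (both reads unique)
readPair <- function(id, pos1, pos2, strand1 = "+", strand2 = "-",
                     chrom = "chr1", len = 50, mapq = 37) {
  data.frame(fragment = id, read = 1:2, chrom = chrom,
             pos = c(pos1, pos2), strand = c(strand1, strand2),
             len = len, mapq = mapq, stringsAsFactors = FALSE)
}

# deletion-signature read pair whose proximal coordinates are (x, y):
# left + read ends at x, right - read starts at y
delPair <- function(id, x, y, len = 50, mapq = 37) {
  readPair(id, x - len + 1, y, "+", "-", len = len, mapq = mapq)
}

# synthetic concordant background: fragments of length `fl` tiling
# [from, to] so coverage is roughly uniform at rate*fl
concordantBackground <- function(from, to, rate, fl = 150, rl = 50,
                                 seed = 1) {
  set.seed(seed)
  n <- rpois(1, rate * (to - from))
  starts <- floor(runif(n, from, to))
  do.call(rbind, lapply(seq_len(n), function(i) {
    readPair(sprintf("bg%05d", i), starts[i], starts[i] + fl - rl, "+",
             "-", len = rl)
  }))
}

# exactness-study parameterization: expected support at the small-instance
# scale and columns in unambiguous likelihood regimes (see the methods
# vignette)
chainTestParams <- function() {
  ModelParams(lambda = 0.04, lavg = 200, readLength = 50, pErr = 0.1)
}
chainTestProblem <- function(A) {
  svProblemFromMatrix(A, chainTestParams(), nA = c(0, 0, 20),
                      nB = c(0, 0, 20))
}
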