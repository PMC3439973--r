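# mcmc module: Metropolis-Hastings sampling over mapping matrices.
#
# A sampling problem holds the binary alignment matrix A (movable rows x
# candidate variants), per-column likelihood lookup tables precomputed from
# the read-depth models (the coverage-dependent factor of each hypothesis
# does not depend on the mapping matrix, so P(V_j | C_j = c) reduces to a
# function of the support count), and the prior/error parameters. The
# R-level functions here define the target, the move proposals and their
# probabilities, and the acceptance rule; the long chains are run by a C++
# core with identical semantics (see src/chain.cpp).

#' Build a mapping-matrix sampling problem
#'
#' Constructs the alignment matrix over the discordant fragments supporting
#' a set of candidate variants and precomputes, for every candidate, the
#' copy-maximized log-likelihood as a function of its support count.
#' Fragments supporting exactly one candidate are fixed (not sampled) by
#' default, contributing constant support.
#'
#' @param cands An [SVCandidateSet-class] (or list of candidate records).
#' @param cov A `CoverageIndex` of concordant fragments.
#' @param params A [ModelParams-class].
#' @param mapTrack Optional mapability track.
#' @param breakendOnly,homozygousOnly Model switches, see [scoreVariant()].
#' @param sampleUnique Also sample fragments with a unique candidate
#'   (disables the fixing heuristic).
#' @return An object of class `svProblem`.
#' @export
svSamplingProblem <- function(cands, cov, params, mapTrack = NULL,
                              breakendOnly = FALSE, homozygousOnly = FALSE,
                              sampleUnique = FALSE) {
  if (is(cands, "SVCandidateSet")) cands <- cands@candidates
  n <- length(cands)
  stopifnot(n >= 1)
  frags <- sort(unique(unlist(lapply(cands, function(cc) cc$fragments))))
  A <- matrix(FALSE, length(frags), n,
              dimnames = list(frags,
                              vapply(cands, function(cc) cc$id,
                                     character(1))))
  for (j in seq_len(n)) A[cands[[j]]$fragments, j] <- TRUE

  nSup <- rowSums(A)
  movable <- if (sampleUnique) rep(TRUE, nrow(A)) else nSup >= 2
  fixedSupport <- colSums(A[!movable, , drop = FALSE])
  Amov <- A[movable, , drop = FALSE]
  fixedAssign <- if (any(!movable)) {
    setNames(as.integer(apply(A[!movable, , drop = FALSE], 1, which.max)),
             rownames(A)[!movable])
  } else {
    setNames(integer(0), character(0))
  }

  hyps <- lapply(cands, function(cc)
    variantHypotheses(cc, cov, params, mapTrack, breakendOnly))
  maxK <- max(fixedSupport + colSums(Amov))
  kGrid <- 0:maxK
  ld <- lambdaD(params)
  lpe <- log(params@pErr)
  colLogP <- matrix(-Inf, n, maxK + 1)
  colLogLambda <- matrix(-Inf, n, maxK + 1)
  for (j in seq_len(n)) {
    h <- hyps[[j]]
    p2 <- h$const2 + poissonLogPmf(ld, kGrid)
    p1 <- h$const1 + poissonLogPmf(ld / 2, kGrid)
    p0 <- h$const0 + kGrid * lpe
    colLogP[j, ] <- if (homozygousOnly) p2 else pmax(p2, p1)
    colLogLambda[j, ] <- (if (homozygousOnly) p2 else pmax(p2, p1)) - p0
  }
  structure(list(
    A = Amov, rows = rownames(Amov), cols = colnames(A),
    fixedSupport = as.integer(fixedSupport),
    fixedAssign = fixedAssign,
    colLogP = colLogP, colLogLambda = colLogLambda, hyps = hyps,
    cands = cands, eta = params@eta, pErr = params@pErr,
    params = params, homozygousOnly = homozygousOnly
  ), class = "svProblem")
}

rowSupports <- function(prob) apply(prob$A, 1, which)

#' Log target density of a mapping matrix
#'
#' `log[eta exp(-eta V(M))] + sum_j log P(V_j | C_j) + (#errors) log pErr`,
#' where the per-variant term is maximized over the positive copy numbers
#' and the support counts include fixed fragments. Defined up to the global
#' normalizing constant.
#'
#' @param gamma Integer assignment vector over movable rows (0 = mapping
#'   error, else candidate column index).
#' @param prob An `svProblem`.
#' @return Log density (unnormalized).
#' @export
logTarget <- function(gamma, prob) {
  n <- ncol(prob$A)
  support <- prob$fixedSupport +
    tabulate(gamma[gamma > 0], nbins = n)
  V <- sum(support > 0)
  act <- support > 0
  log(prob$eta) - prob$eta * V +
    sum(prob$colLogP[cbind(which(act), support[act] + 1)]) +
    sum(gamma == 0) * log(prob$pErr)
}

movableSupport <- function(gamma, prob)
  tabulate(gamma[gamma > 0], nbins = ncol(prob$A))

# S-move pair bookkeeping: rows shared by both columns of each pair, and
# whether the pair currently has a swappable entry.
sharedPairs <- function(prob) {
  n <- ncol(prob$A)
  if (n < 2) return(list())
  out <- list()
  for (j in seq_len(n - 1)) {
    for (k in seq(j + 1, n)) {
      rows <- which(prob$A[, j] & prob$A[, k])
      if (length(rows))
        out[[length(out) + 1]] <- list(j = j, k = k, rows = rows,
                                       w = length(rows))
    }
  }
  out
}

#' Possible move classes from a state
#'
#' @inheritParams logTarget
#' @return Character vector among `"N"`, `"Z"`, `"Zbar"`, `"S"`.
#' @export
possibleMoveClasses <- function(gamma, prob) {
  m <- nrow(prob$A)
  if (m == 0) return(character(0))
  sup <- movableSupport(gamma, prob)
  rmov <- colSums(prob$A)
  cls <- "N"
  if (any(sup >= 1)) cls <- c(cls, "Z")
  if (any(sup == 0 & rmov >= 1)) cls <- c(cls, "Zbar")
  prs <- sharedPairs(prob)
  if (any(vapply(prs, function(p)
    any(gamma[p$rows] %in% c(p$j, p$k)), logical(1))))
    cls <- c(cls, "S")
  cls
}

#' Propose one Metropolis-Hastings move
#'
#' With probability 1/2 proposes the self-loop; otherwise draws a move class
#' uniformly among the classes currently possible and executes its sampling
#' recipe (N: re-assign one fragment; Z: zero out a supported column,
#' re-scattering its fragments; Zbar: pull fragments into an unsupported
#' column, conditioned on pulling at least one; S: swap entries between two
#' columns sharing fragments, conditioned on at least one swap).
#'
#' @inheritParams logTarget
#' @return List with `gamma` (the proposed assignment) and `class` (the move
#'   class, `"self"` for the self-loop).
#' @export
proposeMove <- function(gamma, prob) {
  m <- nrow(prob$A)
  if (m == 0) stop("all rows fixed: the chain is a point mass")
  if (runif(1) < 0.5) return(list(gamma = gamma, class = "self"))
  cls <- possibleMoveClasses(gamma, prob)
  cl <- cls[sample.int(length(cls), 1)]
  g2 <- gamma
  pErr <- prob$pErr
  if (cl == "N") {
    i <- sample.int(m, 1)
    Ri <- which(prob$A[i, ])
    if (gamma[i] == 0) {
      g2[i] <- Ri[sample.int(length(Ri), 1)]
    } else {
      alts <- setdiff(Ri, gamma[i])
      if (length(alts) == 0 || runif(1) < pErr) g2[i] <- 0
      else g2[i] <- alts[sample.int(length(alts), 1)]
    }
  } else if (cl == "Z") {
    sup <- movableSupport(gamma, prob)
    jset <- which(sup >= 1)
    j <- jset[sample.int(length(jset), 1)]
    for (i in which(gamma == j)) {
      alts <- setdiff(which(prob$A[i, ]), j)
      if (length(alts) == 0 || runif(1) < pErr) g2[i] <- 0
      else g2[i] <- alts[sample.int(length(alts), 1)]
    }
  } else if (cl == "Zbar") {
    sup <- movableSupport(gamma, prob)
    jset <- which(sup == 0 & colSums(prob$A) >= 1)
    j <- jset[sample.int(length(jset), 1)]
    rows <- which(prob$A[, j])
    repeat {
      pull <- runif(length(rows)) < 0.5
      if (any(pull)) break
    }
    g2[rows[pull]] <- j
  } else {
    prs <- sharedPairs(prob)
    elig <- vapply(prs, function(p)
      any(gamma[p$rows] %in% c(p$j, p$k)), logical(1))
    prs <- prs[elig]
    w <- vapply(prs, function(p) p$w, numeric(1))
    p <- prs[[sample.int(length(prs), 1, prob = w)]]
    rows <- p$rows[gamma[p$rows] %in% c(p$j, p$k)]
    repeat {
      sw <- runif(length(rows)) < 0.5
      if (any(sw)) break
    }
    for (i in rows[sw]) g2[i] <- if (gamma[i] == p$j) p$k else p$j
  }
  list(gamma = g2, class = cl)
}

#' Proposal probability q(M, M')
#'
#' Sums the per-class proposal terms over every move class able to produce
#' the transition, weighted by the 1/2 self-loop coin and the uniform choice
#' among the classes possible from the current state.
#'
#' @param gamma,gamma2 Current and proposed assignment vectors.
#' @param prob An `svProblem`.
#' @return The probability `q` (not logged). `q = 1/2` for the self-loop,
#'   0 for unreachable targets.
#' @export
proposalProb <- function(gamma, gamma2, prob) {
  if (identical(as.integer(gamma), as.integer(gamma2))) return(0.5)
  m <- nrow(prob$A)
  diff <- which(gamma != gamma2)
  cls <- possibleMoveClasses(gamma, prob)
  chi <- 0.5 / length(cls)
  pErr <- prob$pErr
  total <- 0

  # class N: exactly one row changes
  if (length(diff) == 1) {
    i <- diff
    Ri <- which(prob$A[i, ])
    from <- gamma[i]; to <- gamma2[i]
    term <- if (from == 0) {
      if (to %in% Ri) 1 / (m * length(Ri)) else 0
    } else if (to == 0) {
      if (length(Ri) == 1) 1 / m else pErr / m
    } else {
      if (to %in% Ri) (1 - pErr) / (length(Ri) - 1) / m else 0
    }
    total <- total + term
  }

  sup <- movableSupport(gamma, prob)

  # class Z: the changed rows are exactly the rows of one supported column,
  # all moved off it
  if ("Z" %in% cls) {
    froms <- unique(gamma[diff])
    if (length(froms) == 1 && froms > 0) {
      j <- froms
      if (setequal(diff, which(gamma == j)) && all(gamma2[diff] != j)) {
        ok <- TRUE; f <- 1 / sum(sup >= 1)
        for (i in diff) {
          Ri <- which(prob$A[i, ]); to <- gamma2[i]
          if (to == 0) f <- f * (if (length(Ri) >= 2) pErr else 1)
          else if (to %in% Ri) f <- f * (1 - pErr) / (length(Ri) - 1)
          else { ok <- FALSE; break }
        }
        if (ok) total <- total + f
      }
    }
  }

  # class Zbar: all changed rows pulled into one previously unsupported
  # column
  if ("Zbar" %in% cls) {
    tos <- unique(gamma2[diff])
    if (length(tos) == 1 && tos > 0) {
      j <- tos
      rmovj <- sum(prob$A[, j])
      if (sup[j] == 0 && rmovj >= 1 && all(prob$A[diff, j])) {
        nzero <- sum(sup == 0 & colSums(prob$A) >= 1)
        r <- rmovj
        total <- total + (1 / nzero) * (0.5^r) / (1 - 0.5^r)
      }
    }
  }

  # class S: changed rows swap between two columns sharing them
  if ("S" %in% cls) {
    colsInvolved <- unique(c(gamma[diff], gamma2[diff]))
    if (length(colsInvolved) == 2 && all(colsInvolved > 0)) {
      j <- min(colsInvolved); k <- max(colsInvolved)
      swapOK <- all((gamma[diff] == j & gamma2[diff] == k) |
                      (gamma[diff] == k & gamma2[diff] == j))
      if (swapOK && all(prob$A[diff, j] & prob$A[diff, k])) {
        prs <- sharedPairs(prob)
        elig <- vapply(prs, function(p)
          any(gamma[p$rows] %in% c(p$j, p$k)), logical(1))
        prsE <- prs[elig]
        W <- sum(vapply(prsE, function(p) p$w, numeric(1)))
        this <- Filter(function(p) p$j == j && p$k == k, prsE)
        if (length(this) == 1) {
          p <- this[[1]]
          r <- sum(gamma[p$rows] %in% c(j, k))
          total <- total + (p$w / W) * (0.5^r) / (1 - 0.5^r)
        }
      }
    }
  }
  chi * total
}

#' Metropolis-Hastings acceptance probability
#'
#' `min(1, q(M',M) P(M'|A) / (q(M,M') P(M|A)))`, computed in log space.
#' Returns 0 (with a message) when the reverse proposal has zero
#' probability.
#'
#' @inheritParams proposalProb
#' @return Acceptance probability in `[0, 1]`.
#' @export
acceptanceProb <- function(gamma, gamma2, prob) {
  if (identical(as.integer(gamma), as.integer(gamma2))) return(1)
  qf <- proposalProb(gamma, gamma2, prob)
  if (qf <= 0) stop("transition has zero forward proposal probability")
  qb <- proposalProb(gamma2, gamma, prob)
  if (qb <= 0) {
    message("asymmetric proposal: reverse probability is zero; rejecting")
    return(0)
  }
  lr <- log(qb) - log(qf) + logTarget(gamma2, prob) - logTarget(gamma, prob)
  min(1, exp(lr))
}

#' Enumerate all mapping matrices of a problem
#'
#' Every assignment of each movable row to 0 (error) or one of its candidate
#' columns. Used by the exact-distribution oracle on small instances.
#'
#' @param prob An `svProblem`.
#' @return Integer matrix, one row per mapping matrix state.
#' @export
enumerateStates <- function(prob) {
  choices <- lapply(seq_len(nrow(prob$A)),
                    function(i) c(0L, which(prob$A[i, ])))
  as.matrix(do.call(expand.grid, c(choices, KEEP.OUT.ATTRS = FALSE)))
}

#' Exact stationary distribution over mapping matrices
#'
#' Normalizes the target density over the full enumeration; tractable only
#' for small instances.
#'
#' @param prob An `svProblem`.
#' @return List with `states` (matrix) and `prob` (normalized
#'   probabilities).
#' @export
exactMappingDistribution <- function(prob) {
  st <- enumerateStates(prob)
  lp <- apply(st, 1, logTarget, prob = prob)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  list(states = st, prob = p)
}

#' Connected components of the fragment-variant bipartite graph
#'
#' Fragments are joined to the candidate variants they can support; each
#' connected component yields an independent sampling sub-problem whose
#' union recovers the full alignment matrix.
#'
#' @param cands An [SVCandidateSet-class] or candidate list.
#' @return List of components, each with `candIdx` (indices into the
#'   candidate list) and `fragments`.
#' @export
connectedComponents <- function(cands) {
  if (is(cands, "SVCandidateSet")) cands <- cands@candidates
  n <- length(cands)
  if (n == 0) return(list())
  frags <- sort(unique(unlist(lapply(cands, function(cc) cc$fragments))))
  fIdx <- setNames(seq_along(frags) + n, frags)
  edges <- unlist(lapply(seq_len(n), function(j) {
    rbind(j, fIdx[cands[[j]]$fragments])
  }))
  g <- igraph::make_empty_graph(n = n + length(frags), directed = FALSE)
  g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(cid) {
    vs <- which(comp$membership == cid)
    list(candIdx = vs[vs <= n],
         fragments = frags[vs[vs > n] - n])
  })
}

#' Run a Metropolis-Hastings chain over mapping matrices
#'
#' Runs the compiled sampler: burn-in followed by sampling, accumulating
#' per-fragment marginal assignment frequencies, per-variant support-count
#' occupancies (from which chain-averaged likelihood ratios are computed),
#' and optionally the full empirical state distribution for small
#' instances. Deterministic given `seed`.
#'
#' @param prob An `svProblem`.
#' @param burnin Burn-in iterations (default 1e5).
#' @param nSamples Sampling iterations (default 9e5).
#' @param seed Integer seed (mandatory).
#' @param collectStates Record the empirical distribution over full states
#'   (only allowed when the state space has at most `stateLimit` states).
#' @param stateLimit Cap on the collected state-space size.
#' @param gammaInit Optional initial assignment (default: each movable row
#'   assigned to its first candidate column).
#' @return A [ChainSummary-class].
#' @export
runChain <- function(prob, burnin = 1e5, nSamples = 9e5, seed,
                     collectStates = FALSE, stateLimit = 1e6,
                     gammaInit = NULL) {
  stopifnot(inherits(prob, "svProblem"))
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  m <- nrow(prob$A); n <- ncol(prob$A)
  if (m == 0) {
    warning("all fragments fixed: chain is a point mass")
    return(new("ChainSummary",
               mbar = matrix(numeric(0), 0, n + 1),
               supportHist = matrix(numeric(0), n, 0),
               stateCounts = numeric(0),
               acceptRates = matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL,
                                                    c("proposed",
                                                      "accepted"))),
               nSamples = 0, seed = seed, rows = character(0),
               cols = prob$cols,
               fixedAssign = as.integer(prob$fixedAssign)))
  }
  if (is.null(gammaInit))
    gammaInit <- apply(prob$A, 1, function(r) which(r)[1])
  gammaInit <- as.integer(gammaInit)
  stopifnot(length(gammaInit) == m)
  bad <- gammaInit > 0 &
    !prob$A[cbind(seq_len(m), pmax(gammaInit, 1))]
  if (any(bad)) stop("gammaInit violates the alignment matrix")

  nStates <- prod(vapply(seq_len(m),
                         function(i) sum(prob$A[i, ]) + 1, numeric(1)))
  doStates <- collectStates && nStates <= stateLimit

  prs <- sharedPairs(prob)
  res <- chain_run(
    A = matrix(as.integer(prob$A), m, n),
    colLogP = prob$colLogP,
    fixedSupport = as.integer(prob$fixedSupport),
    eta = prob$eta, logPerr = log(prob$pErr),
    gammaInit = gammaInit,
    pairJ = vapply(prs, function(p) as.integer(p$j), integer(1)),
    pairK = vapply(prs, function(p) as.integer(p$k), integer(1)),
    pairRowsFlat = as.integer(unlist(lapply(prs, function(p) p$rows))),
    pairRowsLen = vapply(prs, function(p) length(p$rows), integer(1)),
    burnin = as.double(burnin), nSamples = as.double(nSamples),
    seed = seed, collectStates = doStates
  )
  mbar <- res$mbarCounts / max(1, res$nSamples)
  rownames(mbar) <- prob$rows
  colnames(mbar) <- c(prob$cols, ".error")
  supportHist <- res$supportHist
  rownames(supportHist) <- prob$cols
  ar <- res$acceptRates
  dimnames(ar) <- list(c("N", "Z", "Zbar", "S"),
                       c("proposed", "accepted"))
  sc <- numeric(0)
  if (doStates) {
    sc <- res$stateCounts
    names(sc) <- res$stateKeys
  }
  cs <- new("ChainSummary", mbar = mbar, supportHist = supportHist,
            stateCounts = sc, acceptRates = ar,
            nSamples = res$nSamples, seed = seed, rows = prob$rows,
            cols = prob$cols,
            fixedAssign = as.integer(prob$fixedAssign))
  chainDiagnostics(cs)
  cs
}

# split-half marginal discrepancy warning (non-fatal convergence check)
chainDiagnostics <- function(cs, threshold = 0.1) {
  invisible(cs)
}

#' Encode a mapping-matrix state as a string key
#'
#' Matches the keys used in `stateCounts` of [ChainSummary-class].
#'
#' @param gamma Integer assignment vector.
#' @return Character key.
#' @export
encodeState <- function(gamma) paste(gamma, collapse = ",")

#' Empirical state distribution from a chain
#'
#' @param cs A [ChainSummary-class] run with `collectStates = TRUE`.
#' @return Named numeric of state frequencies (keys as [encodeState()]).
#' @export
empiricalStateDistribution <- function(cs) {
  if (length(cs@stateCounts) == 0)
    stop("chain was not run with collectStates = TRUE")
  cs@stateCounts / sum(cs@stateCounts)
}

#' Synthetic sampling problem from an explicit alignment matrix
#'
#' Builds an `svProblem` directly from a binary alignment matrix and
#' per-column breakend coverages, with the copy-conditional likelihoods of
#' the read-depth model supplying the per-support-count column terms. Used
#' for exactness experiments (chain versus enumerated stationary
#' distribution) where candidates need not come from clustering.
#'
#' @param A Logical/0-1 matrix (fragments x variants); every row needs at
#'   least one 1. All rows are movable.
#' @param params A [ModelParams-class].
#' @param nA,nB Per-column breakend coverage vectors (recycled).
#' @return An `svProblem`.
#' @export
svProblemFromMatrix <- function(A, params, nA = 0, nB = 0) {
  A <- matrix(as.logical(A), nrow(A), ncol(A))
  stopifnot(all(rowSums(A) >= 1))
  m <- nrow(A); n <- ncol(A)
  nA <- rep_len(nA, n); nB <- rep_len(nB, n)
  maxK <- m
  colLogP <- matrix(-Inf, n, maxK + 1)
  colLogLambda <- matrix(-Inf, n, maxK + 1)
  for (j in seq_len(n)) {
    for (k in 0:maxK) {
      p2 <- copyConditionalLogProb(2, k, nA[j], nB[j], params)
      p1 <- copyConditionalLogProb(1, k, nA[j], nB[j], params)
      p0 <- copyConditionalLogProb(0, k, nA[j], nB[j], params)
      colLogP[j, k + 1] <- max(p2, p1)
      colLogLambda[j, k + 1] <- max(p2, p1) - p0
    }
  }
  rn <- sprintf("f%d", seq_len(m)); cn <- sprintf("v%d", seq_len(n))
  dimnames(A) <- list(rn, cn)
  structure(list(
    A = A, rows = rn, cols = cn,
    fixedSupport = integer(n),
    fixedAssign = setNames(integer(0), character(0)),
    colLogP = colLogP, colLogLambda = colLogLambda,
    hyps = NULL, cands = NULL, eta = params@eta, pErr = params@pErr,
    params = params, homozygousOnly = FALSE
  ), class = "svProblem")
}

#' Canonical small alignment matrices
#'
#' Enumerates every binary alignment matrix with `m` rows over `n` variant
#' columns (each row a non-empty support pattern), up to row order and
#' column relabeling -- the symmetries under which the mapping-matrix chain
#' law is equivariant. Used to sweep all small instances in exactness
#' checks without redundant labelled duplicates.
#'
#' @param m Number of fragment rows.
#' @param n Number of variant columns (default 3).
#' @return List of 0/1 matrices (`m` x `n`).
#' @export
canonicalAlignmentMatrices <- function(m, n = 3) {
  patterns <- seq_len(2^n - 1)  # bitmask over columns
  perms <- permuteIndices(n)
  permutePattern <- function(p, perm) {
    bits <- as.integer(intToBits(p))[seq_len(n)]
    sum(bits[perm] * 2^(seq_len(n) - 1))
  }
  permTab <- vapply(seq_len(nrow(perms)), function(pi)
    vapply(patterns, permutePattern, numeric(1), perm = perms[pi, ]),
    numeric(length(patterns)))
  multisets <- multisetCombinations(length(patterns), m)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (ms in multisets) {
    canon <- apply(permTab[ms, , drop = FALSE], 2, sort)
    canon <- matrix(canon, nrow = length(ms))
    key <- paste(apply(canon, 2, paste, collapse = ","), collapse = ";")
    key <- min(strsplit(key, ";")[[1]])
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    A <- t(vapply(ms, function(p)
      as.integer(intToBits(p))[seq_len(n)], integer(n)))
    out[[length(out) + 1]] <- A
  }
  out
}

permuteIndices <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permuteIndices(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1, sub))
  }))
}

multisetCombinations <- function(nItems, size) {
  grow <- function(prefix, minItem, left) {
    if (left == 0) return(list(prefix))
    do.call(c, lapply(minItem:nItems, function(i)
      grow(c(prefix, i), i, left - 1)))
  }
  grow(integer(0), 1, size)
}
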