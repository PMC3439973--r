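# mcmc: target density, proposals, acceptance, components, chain exactness

test_that("log target matches the closed form on corner states", {
  params <- chainTestParams()
  A <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE)
  prob <- chainTestProblem(A)
  m <- nrow(A)
  # all rows unassigned: log eta + m log pErr
  expect_equal(logTarget(c(0L, 0L), prob),
               log(params@eta) + m * log(params@pErr))
  # single assignment: ratio to the unassigned state is
  # exp(-eta) P(V|chat) / pErr
  lt1 <- logTarget(c(1L, 0L), prob)
  lt0 <- logTarget(c(0L, 0L), prob)
  expect_equal(lt1 - lt0,
               -params@eta + prob$colLogP[1, 2] - log(params@pErr))
})

test_that("log target of independent components adds up in ratios", {
  A1 <- matrix(c(1, 1, 0, 1, 1, 0), 2, 3, byrow = TRUE)
  A2 <- matrix(c(0, 0, 1), 1, 3)
  full <- chainTestProblem(rbind(A1, A2))
  p1 <- chainTestProblem(A1)
  p2 <- chainTestProblem(A2)
  # transition touching only the first component: equal log-ratios
  gFullA <- c(1L, 2L, 3L); gFullB <- c(2L, 2L, 3L)
  g1A <- c(1L, 2L); g1B <- c(2L, 2L)
  expect_equal(
    logTarget(gFullB, full) - logTarget(gFullA, full),
    logTarget(g1B, p1) - logTarget(g1A, p1))
  # and for the second component
  gFullC <- c(1L, 2L, 0L)
  expect_equal(
    logTarget(gFullC, full) - logTarget(gFullA, full),
    logTarget(0L, p2) - logTarget(3L, p2))
})

test_that("proposals respect the mapping-matrix invariants", {
  set.seed(12)
  A <- matrix(c(1, 1, 0, 1, 0, 1, 1, 1, 1), 3, 3, byrow = TRUE)
  prob <- chainTestProblem(A)
  gamma <- c(1L, 1L, 2L)
  for (i in 1:300) {
    pr <- proposeMove(gamma, prob)
    g2 <- pr$gamma
    expect_true(all(g2 >= 0 & g2 <= 3))
    ok <- g2 == 0 | prob$A[cbind(seq_along(g2), pmax(g2, 1))]
    expect_true(all(ok))
    if (pr$class != "self") expect_false(identical(g2, gamma))
    gamma <- g2
  }
})

test_that("a single-candidate assigned row drops with probability pErr under N", {
  # |R_i(A)| = 1: the N move has no alternative column, so the proposal
  # either drops the row (forced) -- the paper's first proposal case
  A <- matrix(1, 1, 1)
  prob <- chainTestProblem(A)
  set.seed(3)
  n <- 20000
  drops <- 0; selfs <- 0
  for (i in seq_len(n)) {
    pr <- proposeMove(1L, prob)
    if (pr$class == "self") selfs <- selfs + 1
    else if (pr$gamma[1] == 0L) drops <- drops + 1
  }
  # non-self proposals from an assigned single-column row always drop
  expect_equal(drops, n - selfs)
  expect_equal(proposalProb(1L, 0L, prob), 0.5 * 1)  # chi * 1/F
  # no zero columns: Zbar not possible
  expect_false("Zbar" %in% possibleMoveClasses(1L, prob))
})

test_that("empirical proposal frequencies match q within Monte Carlo error", {
  A <- matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1, 1, 1, 1), 4, 3, byrow = TRUE)
  prob <- chainTestProblem(A)
  set.seed(8)
  for (gamma in list(c(1L, 1L, 2L, 3L), c(0L, 0L, 0L, 0L),
                     c(2L, 3L, 3L, 0L))) {
    n <- 60000
    tal <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      pr <- proposeMove(gamma, prob)
      k <- paste(pr$gamma, collapse = ",")
      tal[[k]] <- if (is.null(tal[[k]])) 1 else tal[[k]] + 1
    }
    emp <- unlist(as.list(tal)) / n
    for (k in names(emp)) {
      g2 <- as.integer(strsplit(k, ",")[[1]])
      q <- proposalProb(gamma, g2, prob)
      se <- sqrt(max(q * (1 - q), 1e-12) / n)
      expect_lt(abs(emp[k] - q), 4 * se + 2e-3)
    }
    # and no proposable state was assigned q = 0
    expect_true(all(vapply(names(emp), function(k)
      proposalProb(gamma, as.integer(strsplit(k, ",")[[1]]), prob),
      numeric(1)) > 0))
  }
})

test_that("printed proposal cases are reproduced", {
  pe <- chainTestParams()@pErr
  # row with two candidate columns reassigned j -> k:
  # (1/F)(1-pErr)/(|Ri|-1)
  A <- matrix(c(1, 1, 0), 1, 3)
  prob <- chainTestProblem(A)
  q <- proposalProb(1L, 2L, prob)
  # all four classes can produce this transition: N reassigns the row
  # ((1/F)(1-p)/(|Ri|-1)), Z zeroes column 1 re-scattering the row to
  # column 2, Zbar pulls the row into empty column 2, S swaps the (1,2)
  # pair's only row
  cls <- possibleMoveClasses(1L, prob)
  expect_setequal(cls, c("N", "Z", "Zbar", "S"))
  chi <- 0.5 / 4
  expect_equal(q, chi * ((1 - pe) + (1 - pe) + 1 + 1))
  # previously-unassigned row assigned: class term 1/(F |Ri|)
  qUp <- proposalProb(0L, 1L, prob)
  clsU <- possibleMoveClasses(0L, prob)
  chiU <- 0.5 / length(clsU)
  # N: 1/(1*2); Zbar on column 1: (1/2 zero cols)(1/2)/(1-1/2)
  expect_equal(qUp, chiU * (1 / 2 + 1 / 2 * 1))
  # self-loop and unreachable targets
  expect_equal(proposalProb(1L, 1L, prob), 0.5)
  expect_equal(proposalProb(1L, 3L, prob), 0)
})

test_that("acceptance is MH-correct and uses only changed rows and columns", {
  A <- matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1, 1, 1, 1), 4, 3, byrow = TRUE)
  prob <- chainTestProblem(A)
  expect_equal(acceptanceProb(c(1L, 1L, 2L, 3L), c(1L, 1L, 2L, 3L), prob), 1)
  # symmetric two-column instance: alpha(j -> k) = alpha(k -> j)
  As <- matrix(c(1, 1), 1, 2)
  ps <- svProblemFromMatrix(As, chainTestParams(), nA = c(0, 0),
                            nB = c(0, 0))
  expect_equal(acceptanceProb(1L, 2L, ps), acceptanceProb(2L, 1L, ps))
  # random transitions: acceptance ratio equals the full-recompute ratio
  set.seed(15)
  for (i in 1:200) {
    g <- vapply(seq_len(4), function(r) {
      cand <- c(0L, which(prob$A[r, ]))
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    pr <- proposeMove(g, prob)
    if (pr$class == "self") next
    qf <- proposalProb(g, pr$gamma, prob)
    qb <- proposalProb(pr$gamma, g, prob)
    aFull <- min(1, exp(log(qb) + logTarget(pr$gamma, prob) -
                          log(qf) - logTarget(g, prob)))
    expect_equal(acceptanceProb(g, pr$gamma, prob), aFull,
                 tolerance = 1e-12)
  }
})

test_that("bipartite components match a union-find oracle", {
  mkCand <- function(id, frags) list(id = id, fragments = frags)
  # block-diagonal: two components
  cands <- list(mkCand("a", c("f1", "f2")), mkCand("b", c("f3")))
  expect_equal(length(connectedComponents(cands)), 2)
  # shared fragment joins variants
  cands <- list(mkCand("a", c("f1", "f2")), mkCand("b", c("f2", "f3")))
  expect_equal(length(connectedComponents(cands)), 1)
  # random sparse instances
  set.seed(30)
  for (rep in 1:20) {
    nC <- sample(2:6, 1); nF <- sample(2:8, 1)
    frags <- sprintf("f%d", seq_len(nF))
    cands <- lapply(seq_len(nC), function(j)
      mkCand(sprintf("c%d", j),
             sample(frags, sample(seq_len(min(3, nF)), 1))))
    comps <- connectedComponents(cands)
    # oracle: union-find over candidate and fragment nodes
    edges <- do.call(rbind, lapply(seq_len(nC), function(j)
      cbind(j, nC + match(cands[[j]]$fragments, frags))))
    lab <- unionFindComponents(nC + nF, edges)
    usedFrags <- sort(unique(unlist(lapply(cands, `[[`, "fragments"))))
    nExpected <- length(unique(lab[seq_len(nC)]))
    expect_equal(length(comps), nExpected)
    # partition recovers every candidate exactly once
    expect_setequal(unlist(lapply(comps, `[[`, "candIdx")), seq_len(nC))
    for (cp in comps) {
      expect_equal(length(unique(lab[cp$candIdx])), 1)
      expect_setequal(
        cp$fragments,
        sort(unique(unlist(lapply(cands[cp$candIdx], `[[`, "fragments")))))
    }
  }
})

test_that("short chains match exact enumeration and symmetric marginals", {
  # one fragment, one variant with a strong likelihood: mbar tracks the
  # exact two-state stationary probability
  A <- matrix(1, 1, 1)
  prob <- chainTestProblem(A)
  cs <- runChain(prob, burnin = 5e3, nSamples = 1e5, seed = 42,
                 collectStates = TRUE)
  exv <- exactKeyed(prob)
  expect_lt(abs(marginalSupport(cs)[1, 1] - exv["1"]), 0.01)
  # two identical columns: symmetric marginals
  As <- matrix(c(1, 1), 1, 2)
  ps <- svProblemFromMatrix(As, chainTestParams(), nA = c(0, 0), nB = c(0, 0))
  css <- runChain(ps, burnin = 5e3, nSamples = 2e5, seed = 9)
  mb <- marginalSupport(css)
  expect_lt(abs(mb[1, 1] - mb[1, 2]), 0.02)
})

test_that("chains are bit-reproducible for identical seeds", {
  A <- matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1), 3, 3, byrow = TRUE)
  prob <- chainTestProblem(A)
  c1 <- runChain(prob, burnin = 1e4, nSamples = 5e4, seed = 77,
                 collectStates = TRUE)
  c2 <- runChain(prob, burnin = 1e4, nSamples = 5e4, seed = 77,
                 collectStates = TRUE)
  expect_identical(marginalSupport(c1), marginalSupport(c2))
  expect_identical(c1@supportHist, c2@supportHist)
  expect_identical(c1@stateCounts, c2@stateCounts)
  c3 <- runChain(prob, burnin = 1e4, nSamples = 5e4, seed = 78)
  expect_false(identical(marginalSupport(c1), marginalSupport(c3)))
})

test_that("any state is reachable from any other through class-N moves", {
  A <- matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1), 3, 3, byrow = TRUE)
  prob <- chainTestProblem(A)
  sts <- enumerateStates(prob)
  # constructive path: first unassign every differing row, then assign to
  # the target; each step must have positive N proposal probability
  for (i in seq_len(nrow(sts))) {
    g <- sts[sample.int(nrow(sts), 1), ]
    target <- sts[i, ]
    cur <- g
    for (r in which(cur != target)) {
      if (cur[r] != 0) {
        mid <- cur; mid[r] <- 0L
        expect_gt(proposalProb(cur, mid, prob), 0)
        cur <- mid
      }
      if (target[r] != 0) {
        nxt <- cur; nxt[r] <- target[r]
        expect_gt(proposalProb(cur, nxt, prob), 0)
        cur <- nxt
      }
    }
    expect_equal(unname(cur), unname(target))
  }
})

test_that("all fragments fixed yields a degenerate point-mass chain", {
  st <- LibraryStats(150, 250, 200, readLength = 50)
  svf <- pairReads(rbind(delPair("u1", 1000, 2000),
                         delPair("u2", 1040, 2040)), st)
  cov <- coverageIndex(svf)
  cands <- clusterDiscordants(svf)
  prob <- svSamplingProblem(cands, cov, ModelParams(0.3, 200, 50))
  expect_equal(nrow(prob$A), 0)  # unique rows are fixed
  expect_warning(cs <- runChain(prob, seed = 1), "point mass")
  expect_equal(cs@nSamples, 0)
})
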