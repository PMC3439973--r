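# simulator: coordinate maps, fragment sampling statistics, projection,
# truth-geometry consistency, determinism

test_that("haplotype maps encode deletions and inversions correctly", {
  # no SVs: identity
  m0 <- buildHaplotypeMap(1000, data.frame(id = character(0),
                                           svtype = character(0),
                                           a = numeric(0), b = numeric(0),
                                           genotype = integer(0)))
  expect_equal(nrow(m0), 1)
  expect_equal(m0$refStart, 1)
  expect_equal(m0$refEnd, 1000)

  # one deletion [a+1, b-1]: test genome shorter by b-a-1, junction
  # adjacency (a, b)
  sv <- data.frame(id = "d", svtype = "DEL", a = 300, b = 500,
                   genotype = 2L)
  m <- buildHaplotypeMap(1000, sv)
  expect_equal(svprob:::testGenomeLength(m), 1000 - (500 - 300 - 1))
  # base after test position 300 maps to reference 500
  r <- svprob:::mapReadsVec(m, 301, 301, "+")
  expect_equal(r$pos, 500)
  r <- svprob:::mapReadsVec(m, 300, 300, "+")
  expect_equal(r$pos, 300)

  # inversion [a+1, b]: length preserved, strand flips inside, round-trip
  # is bijective off the breakpoints
  svI <- data.frame(id = "i", svtype = "INV", a = 300, b = 500,
                    genotype = 2L)
  mI <- buildHaplotypeMap(1000, svI)
  expect_equal(svprob:::testGenomeLength(mI), 1000)
  inside <- svprob:::mapReadsVec(mI, 301, 301, "+")
  expect_equal(inside$pos, 500)        # first inverted base maps to ref b
  expect_equal(inside$strand, "-")
  refHits <- vapply(1:1000, function(t)
    svprob:::mapReadsVec(mI, t, t, "+")$pos, numeric(1))
  expect_setequal(refHits, 1:1000)     # bijection on single bases

  expect_error(buildHaplotypeMap(1000, data.frame(
    id = c("x", "y"), svtype = "DEL", a = c(100, 150), b = c(200, 400),
    genotype = 2L)), "overlapping")
})

test_that("SV placement respects margins, genotypes and non-overlap", {
  svs <- simulateSVSet(1e6, nDel = 20, nInv = 5, seed = 3)
  expect_equal(sum(svs$svtype == "DEL"), 20)
  expect_equal(sum(svs$svtype == "INV"), 5)
  expect_equal(sum(svs$genotype == 2 & svs$svtype == "DEL"), 10)
  expect_true(all(svs$a < svs$b))
  expect_true(all(diff(svs$a) > 0))
  expect_true(all(svs$a[-1] - svs$b[-nrow(svs)] > 0))
})

test_that("fragment sampling reproduces the Poisson coverage laws", {
  lambda <- 0.3; lavg <- 200; rl <- 50
  refLength <- 4e5
  ident <- data.frame(testStart = 1, testEnd = refLength, refStart = 1,
                      refEnd = refLength, orient = 1)
  maps <- list(ident, ident)
  frags <- sampleFragments(maps, lambda, lavg, 20, rl, seed = 13)
  # expected fragment count lambda * G within 4 sigma
  expN <- lambda * refLength
  expect_lt(abs(nrow(frags) - expN), 4 * sqrt(expN))
  # point coverage at spread-out positions ~ Poisson(lambda * Lavg)
  pts <- seq(5000, refLength - 5000, length.out = 100)
  covCounts <- vapply(pts, function(p)
    sum(frags$start <= p & frags$start + frags$len - 1 >= p), numeric(1))
  lc <- lambda * lavg
  expect_lt(abs(mean(covCounts) - lc), 3 * sqrt(lc / length(pts)))
})

test_that("breakend-spanning fragment counts match lambda_d", {
  lambda <- 0.3; lavg <- 200; rl <- 50
  ld <- (lavg - 2 * rl) * lambda
  sim <- simulateExperiment(refLength = 8e5, nDel = 10, nInv = 0,
                            lambda = lambda, lavg = lavg, sdL = 20,
                            readLength = rl, pErr = 0, seed = 29)
  tt <- sim$truth
  perSV <- table(factor(tt$svId[!is.na(tt$svId)],
                        levels = sim$svs$id[sim$svs$genotype == 2]))
  hom <- sim$svs$id[sim$svs$genotype == 2]
  counts <- as.numeric(perSV[hom])
  expect_lt(abs(mean(counts) - ld), 3 * sqrt(ld / length(counts)))
})

test_that("projection classifies breakpoint fragments with the right signatures", {
  sim <- simulateExperiment(refLength = 3e5, nDel = 3, nInv = 2,
                            lambda = 0.2, pErr = 0, seed = 17)
  al <- fragmentAlignments(sim$fragments)
  tt <- sim$truth
  # fragments away from SVs and repeats align uniquely and concordantly,
  # except the ~0.2% whose lengths fall outside the empirical 0.1%/99.9%
  # quantile bounds
  cls <- fragmentClass(sim$fragments)
  clean <- tt$fragment[is.na(tt$svId)]
  expect_gte(mean(cls[clean] == "concordant-unique"), 0.995)
  outliers <- clean[cls[clean] != "concordant-unique"]
  lens <- tt$len[match(outliers, tt$fragment)]
  expect_true(all(lens < sim$stats@lmin | lens > sim$stats@lmax))
  # deletion-spanning fragments are deletion-signature discordant with
  # span = true length + deleted bases
  for (v in seq_len(nrow(sim$svs))) {
    sv <- sim$svs[v, ]
    supp <- al[al$fragment %in% tt$fragment[!is.na(tt$svId) &
                                              tt$svId == sv$id], ]
    if (nrow(supp) == 0) next
    if (sv$svtype == "DEL") {
      expect_true(all(supp$signature == "deletion"))
      lens <- tt$len[match(supp$fragment, tt$fragment)]
      expect_equal(supp$span, lens + (sv$b - sv$a - 1))
    } else {
      expect_true(all(supp$signature %in% c("inversionPlus",
                                            "inversionMinus")))
    }
  }
})

test_that("true breakend pairs lie inside their supporters' trapezoids", {
  sim <- simulateExperiment(refLength = 3e5, nDel = 4, nInv = 2,
                            lambda = 0.2, pErr = 0, seed = 53)
  al <- fragmentAlignments(sim$fragments)
  tt <- sim$truth
  st <- sim$stats
  # use generous library bounds covering all sampled lengths so the check
  # is about geometry, not the rare length-outlier exclusion
  stWide <- LibraryStats(min(tt$len), max(tt$len), st@lavg,
                         readLength = st@readLength)
  for (v in seq_len(nrow(sim$svs))) {
    sv <- sim$svs[v, ]
    truthAB <- if (sv$svtype == "DEL") {
      list(deletion = c(sv$a, sv$b))
    } else {
      list(inversionPlus = c(sv$a, sv$b),
           inversionMinus = c(sv$a + 1, sv$b + 1))
    }
    supp <- al[al$fragment %in% tt$fragment[!is.na(tt$svId) &
                                              tt$svId == sv$id] &
                 al$status == "discordant", ]
    for (r in seq_len(nrow(supp))) {
      sig <- supp$signature[r]
      if (!sig %in% names(truthAB)) next
      poly <- svprob:::alignmentTrapezoid(supp[r, ], stWide)
      ab <- truthAB[[sig]]
      expect_true(polygonContains(poly, ab[1], ab[2]))
    }
  }
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulateExperiment(refLength = 1e5, nDel = 2, nInv = 1,
                           lambda = 0.1, seed = 99)
  s2 <- simulateExperiment(refLength = 1e5, nDel = 2, nInv = 1,
                           lambda = 0.1, seed = 99)
  expect_identical(fragmentAlignments(s1$fragments),
                   fragmentAlignments(s2$fragments))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$svs, s2$svs)
  s3 <- simulateExperiment(refLength = 1e5, nDel = 2, nInv = 1,
                           lambda = 0.1, seed = 100)
  expect_false(identical(s1$truth, s3$truth))
})

test_that("repeat blocks induce multi-mapped fragments and a zero-mapability track", {
  reps <- data.frame(srcStart = 20000, dstStart = 60000, len = 3000)
  sim <- simulateExperiment(refLength = 1e5, nDel = 0, nInv = 0,
                            lambda = 0.2, pErr = 0, repeats = reps,
                            seed = 7)
  al <- fragmentAlignments(sim$fragments)
  nAln <- table(al$fragment)
  multi <- names(nAln)[nAln > 1]
  expect_gt(length(multi), 0)
  # fragments fully inside one copy have exactly 2 x 2 = 4 read
  # combinations; their class is excluded (one alignment is concordant)
  tt <- sim$truth
  insideBoth <- tt$fragment[tt$r1pos >= 20000 &
                              tt$r2pos + 50 - 1 <= 23000 - 1]
  if (length(insideBoth)) {
    expect_true(all(nAln[insideBoth] == 4))
    cls <- fragmentClass(sim$fragments)
    expect_true(all(cls[insideBoth] == "excluded"))
  }
  tr <- sim$mapTrack
  expect_equal(sum((tr$end - tr$start + 1)[tr$value == 0]), 6000)
  expect_equal(svprob:::mapabilityFraction(tr, "chr1", 20000, 22999), 0)
  expect_equal(mapabilityFraction(tr, "chr1", 1, 19999), 1)
})
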