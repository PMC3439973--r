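# simulator module: rearranged diploid test genomes and paired-end fragment
# sampling with the exact statistical structure the probability model
# assumes (uniform Poisson-process fragment starts, Normal fragment
# lengths, technology-consistent read orientations, optional repeat blocks
# inducing multi-mapped reads, and a configurable erroneous-mapping rate).

#' Draw a set of non-overlapping structural variants
#'
#' Places deletions and inversions uniformly on a synthetic reference,
#' keeping a guard margin between events, and assigns genotypes
#' (homozygous: both haplotypes; heterozygous: one haplotype).
#'
#' @param refLength Reference length (bases).
#' @param nDel,nInv Number of deletions and inversions.
#' @param delLen,invLen Length ranges (min, max) for each class.
#' @param homFraction Fraction of events that are homozygous (default 0.5).
#' @param margin Minimum distance between events and from the reference
#'   ends (default 5000).
#' @param seed Integer seed (mandatory).
#' @return Data.frame with columns `id`, `svtype`, `a`, `b`, `genotype`.
#'   For a deletion the interval `[a+1, b-1]` is removed, creating the
#'   novel adjacency (a, b). For an inversion the segment `[a+1, b]` is
#'   reversed, creating adjacencies (a, b) (+/+ signature) and
#'   (a+1, b+1) (-/- signature).
#' @export
simulateSVSet <- function(refLength, nDel = 50, nInv = 10,
                          delLen = c(400, 3000), invLen = c(600, 5000),
                          homFraction = 0.5, margin = 5000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- nDel + nInv
  lens <- c(round(runif(nDel, delLen[1], delLen[2])),
            round(runif(nInv, invLen[1], invLen[2])))
  types <- c(rep("DEL", nDel), rep("INV", nInv))
  # place left ends greedily with rejection, keeping margins
  placed <- matrix(numeric(0), ncol = 2)
  starts <- numeric(n)
  for (i in order(-lens)) {
    ok <- FALSE
    for (try in 1:2000) {
      s <- round(runif(1, margin, refLength - margin - lens[i]))
      e <- s + lens[i]
      if (nrow(placed) == 0 ||
          all(e + margin < placed[, 1] | s - margin > placed[, 2])) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", n, " events on ", refLength,
                  " bases; increase refLength or reduce counts")
    placed <- rbind(placed, c(s, e))
    starts[i] <- s
  }
  geno <- integer(n)
  for (tt in unique(types)) {
    idx <- which(types == tt)
    nHom <- round(homFraction * length(idx))
    geno[idx] <- c(rep(2L, nHom), rep(1L, length(idx) - nHom))
  }
  sv <- data.frame(
    id = sprintf("sim%03d", seq_len(n)),
    svtype = types,
    a = starts, b = starts + lens,
    genotype = geno, stringsAsFactors = FALSE)
  sv[order(sv$a), ]
}

#' Build a haplotype coordinate map
#'
#' Applies a set of SVs to the reference, producing a piecewise-linear map
#' between test-genome and reference coordinates. Deletions remove
#' `[a+1, b-1]`; inversions reverse `[a+1, b]`.
#'
#' @param refLength Reference length.
#' @param svs SV table rows (see [simulateSVSet()]) carried by this
#'   haplotype; must be non-overlapping.
#' @return Data.frame of segments with columns `testStart`, `testEnd`,
#'   `refStart`, `refEnd`, `orient` (+1 forward, -1 inverted).
#' @export
buildHaplotypeMap <- function(refLength, svs) {
  svs <- svs[order(svs$a), , drop = FALSE]
  if (nrow(svs) >= 2 && any(svs$a[-1] <= svs$b[-nrow(svs)]))
    stop("overlapping SVs on one haplotype")
  segs <- list()
  refPos <- 1   # next unconsumed reference base
  testPos <- 1
  addSeg <- function(refStart, refEnd, orient) {
    len <- refEnd - refStart + 1
    if (len <= 0) return(invisible())
    segs[[length(segs) + 1]] <<- data.frame(
      testStart = testPos, testEnd = testPos + len - 1,
      refStart = refStart, refEnd = refEnd, orient = orient)
    testPos <<- testPos + len
  }
  for (i in seq_len(nrow(svs))) {
    a <- svs$a[i]; b <- svs$b[i]
    if (svs$svtype[i] == "DEL") {
      addSeg(refPos, a, +1)     # up to and including breakend a
      refPos <- b               # deleted [a+1, b-1]; resume at b
    } else {
      addSeg(refPos, a, +1)
      addSeg(a + 1, b, -1)      # inverted segment
      refPos <- b + 1
    }
  }
  addSeg(refPos, refLength, +1)
  do.call(rbind, segs)
}

testGenomeLength <- function(map) sum(map$testEnd - map$testStart + 1)

# Map a read [t1, t2] (test coordinates, strand) through the haplotype map.
# Reads crossing a segment boundary fail to align (breakpoint-containing
# reads), mirroring full-length alignment to the reference.
mapReadThrough <- function(map, t1, t2, strand) {
  m <- mapReadsVec(map, t1, t2, strand)
  if (is.na(m$pos[1])) return(NULL)
  list(pos = m$pos[1], strand = m$strand[1])
}

# vectorized version: map is sorted by testStart
mapReadsVec <- function(map, t1, t2, strand) {
  seg <- findInterval(t1, map$testStart)
  bad <- seg < 1 | t2 > map$testEnd[pmax(seg, 1)] | t2 < t1
  seg[bad] <- NA_integer_
  fwd <- map$orient[seg] == 1
  pos <- ifelse(fwd, map$refStart[seg] + (t1 - map$testStart[seg]),
                map$refEnd[seg] - (t2 - map$testStart[seg]))
  str <- ifelse(fwd, strand, ifelse(strand == "+", "-", "+"))
  list(pos = pos, strand = str, seg = seg)
}

#' Sample paired-end fragments from a diploid test genome
#'
#' Fragment left ends follow a Poisson process at rate `lambda/2` per
#' haplotype base (so diploid coverage matches `lambda`); lengths are
#' Normal(`lavg`, `sdL`) truncated below at twice the read length; reads of
#' `readLength` bases are taken from the fragment ends with Illumina
#' orientation (left +, right -).
#'
#' @param maps List of two haplotype maps from [buildHaplotypeMap()].
#' @param lambda Diploid fragment rate per base.
#' @param lavg,sdL Fragment length mean and standard deviation.
#' @param readLength Read length (bases).
#' @param seed Integer seed (mandatory).
#' @return Data.frame of fragments with test coordinates and haplotype.
#' @export
sampleFragments <- function(maps, lambda, lavg = 200, sdL = 20,
                            readLength = 50, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(lavg > 2 * readLength)
  set.seed(seed)
  out <- list()
  for (h in 1:2) {
    gl <- testGenomeLength(maps[[h]])
    nf <- rpois(1, lambda / 2 * gl)
    len <- pmax(2 * readLength, round(rnorm(nf, lavg, sdL)))
    start <- floor(runif(nf, 1, gl - len + 1))
    out[[h]] <- data.frame(haplotype = h, start = start, len = len)
  }
  frags <- do.call(rbind, out)
  frags$fragment <- sprintf("frag%07d", seq_len(nrow(frags)))
  frags
}

#' Project simulated fragments onto the reference
#'
#' Maps each read through its haplotype's coordinate map (reads containing
#' a breakpoint fail to align and drop the fragment), adds alternative
#' placements for reads falling inside configured repeat blocks, and
#' replaces a fraction `pErr` of fragment placements with random erroneous
#' discordant placements. Returns read-level alignment records plus a truth
#' table.
#'
#' @param frags Fragment table from [sampleFragments()].
#' @param maps List of two haplotype maps.
#' @param svs The SV table (for truth annotation).
#' @param refLength Reference length.
#' @param readLength Read length.
#' @param repeats Optional data.frame of homologous block pairs (columns
#'   `srcStart`, `dstStart`, `len`): a read fully inside one copy gains an
#'   additional alignment at the homologous position in the other.
#' @param pErr Erroneous-mapping fraction.
#' @param chrom Chromosome name for the synthetic reference.
#' @param seed Integer seed (mandatory).
#' @return List with `reads` (read-level table for [pairReads()]) and
#'   `truth` (per-fragment table: placement, `svId` for breakpoint-spanning
#'   fragments, `erroneous` flag).
#' @export
projectAlignments <- function(frags, maps, svs, refLength, readLength = 50,
                              repeats = NULL, pErr = 0.01, chrom = "chr1",
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- nrow(frags)
  r1pos <- rep(NA_real_, n); r1str <- rep(NA_character_, n)
  r2pos <- rep(NA_real_, n); r2str <- rep(NA_character_, n)
  seg1 <- rep(NA_integer_, n); seg2 <- rep(NA_integer_, n)
  for (h in 1:2) {
    hi <- which(frags$haplotype == h)
    if (!length(hi)) next
    map <- maps[[h]]
    s <- frags$start[hi]; L <- frags$len[hi]
    m1 <- mapReadsVec(map, s, s + readLength - 1, rep("+", length(hi)))
    m2 <- mapReadsVec(map, s + L - readLength, s + L - 1,
                      rep("-", length(hi)))
    r1pos[hi] <- m1$pos; r1str[hi] <- m1$strand; seg1[hi] <- m1$seg
    r2pos[hi] <- m2$pos; r2str[hi] <- m2$strand; seg2[hi] <- m2$seg
  }
  mapped <- !is.na(r1pos) & !is.na(r2pos)
  # breakpoint-spanning fragments: reads land in different map segments;
  # annotate with the SV whose breakend region the mapped pair brackets
  svId <- rep(NA_character_, n)
  span <- mapped & seg1 != seg2
  if (any(span) && nrow(svs)) {
    lo <- pmin(r1pos, r2pos); hi2 <- pmax(r1pos, r2pos) + readLength - 1
    for (v in seq_len(nrow(svs))) {
      inSV <- span & lo <= svs$b[v] + 1 & hi2 >= svs$a[v] - 1
      svId[inSV & is.na(svId)] <- svs$id[v]
    }
  }
  frags <- cbind(frags, r1pos = r1pos, r1str = r1str, r2pos = r2pos,
                 r2str = r2str, mapped = mapped, svId = svId,
                 stringsAsFactors = FALSE)
  frags <- frags[frags$mapped, , drop = FALSE]
  nm <- nrow(frags)

  # erroneous placements: replace the true placement of a random fraction
  err <- runif(nm) < pErr
  if (any(err)) {
    ne <- sum(err)
    p1 <- floor(runif(ne, 1, refLength - 1e4))
    gap <- floor(runif(ne, 2 * readLength + 1, 1e4))
    s1 <- sample(c("+", "-"), ne, replace = TRUE)
    s2 <- sample(c("+", "-"), ne, replace = TRUE)
    frags$r1pos[err] <- p1
    frags$r1str[err] <- s1
    frags$r2pos[err] <- p1 + gap
    frags$r2str[err] <- s2
    frags$svId[err] <- NA_character_
  }
  frags$erroneous <- err

  mk <- function(read, pos, str) {
    data.frame(fragment = frags$fragment, read = read, chrom = chrom,
               pos = pos, strand = str, len = readLength, mapq = 37L,
               stringsAsFactors = FALSE)
  }
  reads <- rbind(mk(1L, frags$r1pos, frags$r1str),
                 mk(2L, frags$r2pos, frags$r2str))

  # repeat blocks: alternative placement in the homologous copy
  if (!is.null(repeats) && nrow(repeats)) {
    extra <- list()
    for (r in seq_len(nrow(repeats))) {
      for (dir in 1:2) {
        from <- if (dir == 1) repeats$srcStart[r] else repeats$dstStart[r]
        to <- if (dir == 1) repeats$dstStart[r] else repeats$srcStart[r]
        inBlock <- reads$pos >= from &
          reads$pos + readLength - 1 <= from + repeats$len[r] - 1
        if (any(inBlock)) {
          alt <- reads[inBlock, , drop = FALSE]
          alt$pos <- alt$pos - from + to
          extra[[length(extra) + 1]] <- alt
        }
      }
    }
    if (length(extra)) reads <- rbind(reads, do.call(rbind, extra))
  }
  truth <- frags[, c("fragment", "haplotype", "start", "len", "r1pos",
                     "r2pos", "svId", "erroneous")]
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

#' Mapability track of a simulated reference
#'
#' R = 0 inside configured repeat blocks (bases whose reads have
#' non-unique placements), R = 1 elsewhere.
#'
#' @param refLength Reference length.
#' @param repeats Repeat table as in [projectAlignments()].
#' @param chrom Chromosome name.
#' @return BED-graph-like data.frame (`chrom`, `start`, `end`, `value`).
#' @export
simulatedMapability <- function(refLength, repeats = NULL,
                                chrom = "chr1") {
  if (is.null(repeats) || nrow(repeats) == 0) {
    return(data.frame(chrom = chrom, start = 1, end = refLength,
                      value = 1, stringsAsFactors = FALSE))
  }
  blocks <- rbind(
    data.frame(start = repeats$srcStart,
               end = repeats$srcStart + repeats$len - 1),
    data.frame(start = repeats$dstStart,
               end = repeats$dstStart + repeats$len - 1))
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  out <- list()
  pos <- 1
  for (i in seq_len(nrow(blocks))) {
    if (blocks$start[i] > pos)
      out[[length(out) + 1]] <- data.frame(start = pos,
                                           end = blocks$start[i] - 1,
                                           value = 1)
    out[[length(out) + 1]] <- data.frame(start = blocks$start[i],
                                         end = blocks$end[i], value = 0)
    pos <- blocks$end[i] + 1
  }
  if (pos <= refLength)
    out[[length(out) + 1]] <- data.frame(start = pos, end = refLength,
                                         value = 1)
  res <- do.call(rbind, out)
  data.frame(chrom = chrom, start = res$start, end = res$end,
             value = res$value, stringsAsFactors = FALSE)
}

#' Simulate a full paired-end experiment
#'
#' Convenience driver: draws SVs, builds the two haplotype maps, samples
#' fragments, projects alignments, and pairs reads into an
#' [SVFragments-class] ready for the calling pipeline.
#'
#' @param refLength Reference length (default 5e6).
#' @param nDel,nInv Event counts (defaults 50 and 10).
#' @param lambda Diploid fragment rate per base (default 0.3).
#' @param lavg,sdL,readLength Fragment length model (defaults 200/20/50).
#' @param pErr Erroneous-mapping fraction (default 0.01).
#' @param repeats Optional repeat-block table.
#' @param stats Optional [LibraryStats-class]; estimated from the simulated
#'   concordant spans when `NULL`.
#' @param seed Integer seed (mandatory).
#' @return List with `fragments` ([SVFragments-class]), `svs`, `truth`,
#'   `mapTrack`, `params` ([ModelParams-class]), `refLength`.
#' @export
simulateExperiment <- function(refLength = 5e6, nDel = 50, nInv = 10,
                               lambda = 0.3, lavg = 200, sdL = 20,
                               readLength = 50, pErr = 0.01,
                               repeats = NULL, stats = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  svs <- simulateSVSet(refLength, nDel = nDel, nInv = nInv, seed = seed)
  maps <- list(
    buildHaplotypeMap(refLength, svs[svs$genotype == 2, , drop = FALSE]),
    buildHaplotypeMap(refLength, svs[svs$genotype >= 1, , drop = FALSE]))
  frags <- sampleFragments(maps, lambda, lavg, sdL, readLength,
                           seed = seed + 1L)
  proj <- projectAlignments(frags, maps, svs, refLength, readLength,
                            repeats = repeats, pErr = pErr,
                            seed = seed + 2L)
  if (is.null(stats)) {
    spans <- proj$truth$len[is.na(proj$truth$svId) & !proj$truth$erroneous]
    stats <- estimateLengthBounds(spans, readLength = readLength)
  }
  svf <- pairReads(proj$reads, stats)
  # the scoring model needs a strictly positive error probability even for
  # error-free simulations
  params <- ModelParams(lambda = lambda, lavg = stats@lavg,
                        readLength = readLength,
                        pErr = if (pErr > 0) pErr else 0.01)
  list(fragments = svf, svs = svs, truth = proj$truth,
       mapTrack = simulatedMapability(refLength, repeats),
       params = params, refLength = refLength, stats = stats)
}
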