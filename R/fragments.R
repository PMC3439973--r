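# io_fragments module: pairing, concordance classification, library-stat
# estimation, alignment filters, and concordant coverage counting.

# findInterval on vectors that are sorted by construction: binary search
# without the O(n) sortedness validation findInterval performs per call
fi <- function(x, vec) count_le(as.numeric(x), vec)

# Breakpoint-proximal coordinate of a read: rightmost aligned base for a
# +-strand read, leftmost for a --strand read.
proximalCoord <- function(pos, strand, len) {
  ifelse(strand == "+", pos + len - 1, pos)
}

#' Pair read-level alignment records into fragment alignments
#'
#' Takes one row per read alignment and forms every fragment alignment (one
#' alignment chosen for each read of the pair), classifying each as
#' concordant or discordant against the library statistics. Reads are
#' re-ordered within each pair so that the breakpoint-proximal coordinates
#' satisfy `x < y` (same chromosome) or `chromX <= chromY`.
#'
#' @param reads A data.frame with columns `fragment`, `read` (1 or 2),
#'   `chrom`, `pos` (1-based leftmost aligned base), `strand` (`"+"`/`"-"`),
#'   `len` (aligned read length), and optionally `mapq`.
#' @param stats A [LibraryStats-class].
#' @return An [SVFragments-class] with one row per fragment alignment and
#'   the fragment partition filled in (see [partitionFragments()]).
#' @export
pairReads <- function(reads, stats) {
  stopifnot(is(stats, "LibraryStats"))
  need <- c("fragment", "read", "chrom", "pos", "strand", "len")
  if (!all(need %in% names(reads)))
    stop("reads must have columns: ", paste(need, collapse = ", "))
  bad <- !reads$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " read records with unknown strand symbol rejected")
    reads <- reads[!bad, , drop = FALSE]
  }
  if (is.null(reads$mapq)) reads$mapq <- 60L
  stopifnot(all(reads$pos >= 1), all(reads$len >= 1))

  r1 <- reads[reads$read == 1, , drop = FALSE]
  r2 <- reads[reads$read == 2, , drop = FALSE]
  keep <- intersect(unique(r1$fragment), unique(r2$fragment))
  r1 <- r1[r1$fragment %in% keep, , drop = FALSE]
  r2 <- r2[r2$fragment %in% keep, , drop = FALSE]

  # cross product of read-1 and read-2 alignments within each fragment;
  # fast path for the (typical) unique-unique case
  n1 <- table(r1$fragment); n2 <- table(r2$fragment)
  uniq <- keep[n1[keep] == 1 & n2[keep] == 1]
  multi <- setdiff(keep, uniq)
  aU <- match(uniq, r1$fragment)
  bU <- match(uniq, r2$fragment)
  if (length(multi)) {
    i1 <- split(seq_len(nrow(r1)), r1$fragment)
    i2 <- split(seq_len(nrow(r2)), r2$fragment)
    combos <- lapply(multi, function(f) {
      expand.grid(a = i1[[f]], b = i2[[f]], KEEP.OUT.ATTRS = FALSE)
    })
    combos <- do.call(rbind, combos)
    a <- c(aU, combos$a); b <- c(bU, combos$b)
  } else {
    a <- aU; b <- bU
  }

  al <- data.frame(
    fragment = as.character(r1$fragment[a]),
    chrom1 = r1$chrom[a], pos1 = r1$pos[a], strand1 = r1$strand[a],
    len1 = r1$len[a], mapq1 = r1$mapq[a],
    chrom2 = r2$chrom[b], pos2 = r2$pos[b], strand2 = r2$strand[b],
    len2 = r2$len[b], mapq2 = r2$mapq[b],
    stringsAsFactors = FALSE
  )
  al <- classifyAlignments(al, stats)
  svf <- new("SVFragments", alignments = al, stats = stats,
             fragClass = character(0))
  partitionFragments(svf)
}

# Vectorized classification of paired alignments. Input columns
# chrom1/pos1/strand1/len1 (read 1) and the read-2 counterparts; output adds
# the proximal coordinates x < y, signs, span, status and signature.
classifyAlignments <- function(al, stats) {
  # order within pair: left = smaller coordinate (same chrom), else by chrom
  p1 <- proximalCoord(al$pos1, al$strand1, al$len1)
  p2 <- proximalCoord(al$pos2, al$strand2, al$len2)
  swap <- (al$chrom1 > al$chrom2) | (al$chrom1 == al$chrom2 & p1 > p2)

  pick <- function(f1, f2) ifelse(swap, f2, f1)
  out <- data.frame(
    fragment = al$fragment,
    chromX = pick(al$chrom1, al$chrom2),
    posX = pick(al$pos1, al$pos2),
    strandX = pick(al$strand1, al$strand2),
    lenX = pick(al$len1, al$len2),
    chromY = pick(al$chrom2, al$chrom1),
    posY = pick(al$pos2, al$pos1),
    strandY = pick(al$strand2, al$strand1),
    lenY = pick(al$len2, al$len1),
    mateX = ifelse(swap, 2L, 1L),
    mapq = pmin(al$mapq1, al$mapq2),
    stringsAsFactors = FALSE
  )
  out$x <- proximalCoord(out$posX, out$strandX, out$lenX)
  out$y <- proximalCoord(out$posY, out$strandY, out$lenY)
  out$signX <- ifelse(out$strandX == "+", 1, -1)
  out$signY <- ifelse(out$strandY == "+", 1, -1)
  same <- out$chromX == out$chromY
  # outermost mapped extent of the pair
  lo <- pmin(out$posX, out$posY)
  hi <- pmax(out$posX + out$lenX - 1, out$posY + out$lenY - 1)
  out$span <- ifelse(same, hi - lo + 1, NA_real_)

  convergent <- isConvergent(out, stats@technology)
  sig <- rep("translocation", nrow(out))
  sig[same & out$strandX == "+" & out$strandY == "+"] <- "inversionPlus"
  sig[same & out$strandX == "-" & out$strandY == "-"] <- "inversionMinus"
  sig[same & convergent & out$span > stats@lmax] <- "deletion"
  sig[same & convergent & out$span < stats@lmin] <- "divergent"
  sig[same & !convergent & out$strandX == "-" & out$strandY == "+" &
        stats@technology == "illumina-convergent"] <- "divergent"
  conc <- same & convergent & out$span >= stats@lmin & out$span <= stats@lmax
  out$status <- ifelse(conc, "concordant", "discordant")
  out$signature <- ifelse(conc, "concordant", sig)
  # degenerate same-position pairs cannot define an ordered adjacency; treat
  # as divergent with a nominal 1-base offset to keep x < y
  eq <- same & out$x == out$y
  if (any(eq)) {
    out$y[eq] <- out$y[eq] + 1
    out$status[eq] <- "discordant"
    out$signature[eq] <- "divergent"
  }
  out
}

# Convergent-orientation rule per technology. For Illumina paired-end data
# the left read is forward and the right read reverse (+/-). For SOLiD both
# reads come from the same strand: +/+ when the first-sequenced read has the
# smaller coordinate, -/- when it has the larger.
isConvergent <- function(out, technology) {
  same <- out$chromX == out$chromY
  if (technology == "illumina-convergent") {
    same & out$strandX == "+" & out$strandY == "-"
  } else {
    sameStrand <- out$strandX == out$strandY
    plusOK <- out$strandX == "+" & out$mateX == 1L
    minusOK <- out$strandX == "-" & out$mateX == 2L
    same & sameStrand & (plusOK | minusOK)
  }
}

#' Classify a single fragment alignment
#'
#' Convenience scalar wrapper around the vectorized classifier: returns the
#' concordance status and discordant signature for one pair of read
#' alignments.
#'
#' @param chrom1,pos1,strand1,len1 Read-1 alignment.
#' @param chrom2,pos2,strand2,len2 Read-2 alignment.
#' @param stats A [LibraryStats-class].
#' @return A one-row data.frame with `x`, `y`, `signX`, `signY`, `span`,
#'   `status` and `signature`.
#' @examples
#' st <- LibraryStats(100, 293, 200, readLength = 50)
#' classifyFragment("chr1", 1000, "+", 50, "chr1", 1130, "-", 50, st)$status
#' @export
classifyFragment <- function(chrom1, pos1, strand1, len1,
                             chrom2, pos2, strand2, len2, stats) {
  if (!strand1 %in% c("+", "-") || !strand2 %in% c("+", "-"))
    stop("unknown strand symbol")
  al <- data.frame(fragment = "f", chrom1 = chrom1, pos1 = pos1,
                   strand1 = strand1, len1 = len1, mapq1 = 60L,
                   chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
                   len2 = len2, mapq2 = 60L, stringsAsFactors = FALSE)
  classifyAlignments(al, stats)
}

#' Estimate fragment-length bounds from concordant spans
#'
#' Derives `[Lmin, Lmax]` from the empirical distribution of mapped fragment
#' spans: by default the 0.1% and 99.9% quantiles; alternatively
#' mean +/- k standard deviations. `Lavg` is the mean span.
#'
#' @param spans Numeric vector of mapped spans of (putatively concordant)
#'   fragments.
#' @param method `"quantile"` or `"sd"`.
#' @param level Tail probability for the quantile rule (default 0.001).
#' @param k Number of standard deviations for the `"sd"` rule.
#' @param readLength,technology Passed through to [LibraryStats()].
#' @param override Optional [LibraryStats-class]; returned unchanged when
#'   supplied (configuration passthrough).
#' @return A [LibraryStats-class].
#' @export
estimateLengthBounds <- function(spans, method = c("quantile", "sd"),
                                 level = 0.001, k = 3, readLength = 50,
                                 technology = "illumina-convergent",
                                 override = NULL) {
  if (!is.null(override)) {
    stopifnot(is(override, "LibraryStats"))
    return(override)
  }
  method <- match.arg(method)
  spans <- spans[is.finite(spans)]
  if (length(spans) < 100)
    stop("need at least 100 concordant spans to estimate bounds; ",
         "supply Lmin/Lmax explicitly via LibraryStats()")
  if (method == "quantile") {
    q <- unname(quantile(spans, c(level, 1 - level), type = 7))
    lmin <- q[1]; lmax <- q[2]
  } else {
    m <- mean(spans); s <- stats::sd(spans)
    lmin <- m - k * s; lmax <- m + k * s
  }
  LibraryStats(lmin, lmax, lavg = mean(spans), readLength = readLength,
               technology = technology)
}

#' Apply the standard mapping filters
#'
#' Drops fragment alignments with mapping quality not exceeding `minMapq`
#' (strict inequality: `mapq > minMapq` is kept) or same-chromosome span
#' above `maxSpan`, and removes entire fragments whose reads have more than
#' `maxAlignments` alignments genome-wide.
#'
#' @param x An [SVFragments-class].
#' @param minMapq Minimum mapping quality (exclusive); default 10.
#' @param maxSpan Maximum same-chromosome mapped distance; default 5e5.
#' @param maxAlignments Maximum genome-wide alignment count per fragment
#'   (read-level alignments summed over both reads); default 100.
#' @return A filtered [SVFragments-class] (partition recomputed; fragments
#'   whose alignments are all removed remain in the partition as
#'   `"excluded"`).
#' @export
filterAlignments <- function(x, minMapq = 10, maxSpan = 5e5,
                             maxAlignments = 100) {
  stopifnot(is(x, "SVFragments"))
  al <- x@alignments
  allFrags <- unique(al$fragment)
  # genome-wide read alignment count: distinct read placements per fragment
  key1 <- paste(al$fragment, al$mateX, al$chromX, al$posX, al$strandX)
  key2 <- paste(al$fragment, 3L - al$mateX, al$chromY, al$posY, al$strandY)
  nAln <- rowsum(as.integer(!duplicated(c(key1, key2))),
                 c(al$fragment, al$fragment))
  tooMany <- rownames(nAln)[nAln[, 1] > maxAlignments]

  keep <- al$mapq > minMapq &
    !(al$chromX == al$chromY & al$span > maxSpan) &
    !(al$fragment %in% tooMany)
  x@alignments <- al[keep, , drop = FALSE]
  partitionFragments(x, allFragments = allFrags)
}

#' Partition fragments into concordant-unique / discordant / excluded
#'
#' A fragment is `concordant-unique` when it has exactly one alignment and
#' that alignment is concordant; `discordant` when every alignment is
#' discordant; otherwise `excluded` (multiple alignments at least one of
#' which is concordant, or no surviving alignments).
#'
#' @param x An [SVFragments-class].
#' @param allFragments Optional character vector of fragment ids that should
#'   appear in the partition even if they no longer have alignments.
#' @return `x` with the `fragClass` slot filled.
#' @export
partitionFragments <- function(x, allFragments = NULL) {
  al <- x@alignments
  ids <- unique(c(al$fragment, allFragments))
  n <- tabulate(factor(al$fragment, levels = ids), nbins = length(ids))
  nConc <- tabulate(factor(al$fragment[al$status == "concordant"],
                           levels = ids), nbins = length(ids))
  cls <- rep("excluded", length(ids))
  cls[n == 1 & nConc == 1] <- "concordant-unique"
  cls[n >= 1 & nConc == 0] <- "discordant"
  x@fragClass <- setNames(cls, ids)
  x
}

#' Index of concordant fragment extents for coverage queries
#'
#' Builds a per-chromosome interval index of the full mapped extents
#' `[leftmost base of the left read, rightmost base of the right read]` of
#' concordant-unique fragments.
#'
#' @param x An [SVFragments-class] (partition must be filled).
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   warn on out-of-bounds queries.
#' @return An object of class `CoverageIndex` (list-based) accepted by
#'   [concordantCoverage()].
#' @export
coverageIndex <- function(x, seqlengths = NULL) {
  stopifnot(is(x, "SVFragments"))
  al <- x@alignments
  conc <- names(x@fragClass)[x@fragClass == "concordant-unique"]
  al <- al[al$status == "concordant" & al$fragment %in% conc, , drop = FALSE]
  start <- pmin(al$posX, al$posY)
  end <- pmax(al$posX + al$lenX - 1, al$posY + al$lenY - 1)
  byChrom <- split(seq_along(start), al$chromX)
  # sorted endpoint vectors: n(p) = #(start <= p) - #(end < p), each an
  # O(log n) findInterval lookup
  idx <- lapply(byChrom, function(i) {
    list(starts = sort(start[i]), ends = sort(end[i]))
  })
  structure(list(ranges = idx, seqlengths = seqlengths),
            class = "CoverageIndex")
}

#' Concordant coverage at points or intervals
#'
#' `n(p)`: the number of concordant fragments whose full mapped extent
#' contains point `p`; `n(I)`: the number whose extent intersects the
#' interval `I = [from, to]`.
#'
#' @param cov A `CoverageIndex` from [coverageIndex()].
#' @param chrom Chromosome.
#' @param at Integer vector of points (for point queries).
#' @param from,to Interval bounds (for interval queries; supply instead of
#'   `at`).
#' @return Integer vector of counts.
#' @export
concordantCoverage <- function(cov, chrom, at = NULL, from = NULL,
                               to = NULL) {
  stopifnot(inherits(cov, "CoverageIndex"))
  ix <- cov$ranges[[chrom]]
  if (is.null(at)) {
    stopifnot(!is.null(from), !is.null(to), length(from) == length(to))
    lo <- pmin(from, to); hi <- pmax(from, to)
  } else {
    lo <- hi <- at
  }
  sl <- cov$seqlengths
  if (!is.null(sl) && chrom %in% names(sl)) {
    if (any(lo < 1 | hi > sl[[chrom]]))
      warning("coverage query outside reference bounds for ", chrom,
              "; returning 0 there")
  }
  if (is.null(ix)) return(integer(length(lo)))
  # extents intersecting [lo, hi]: start <= hi and end >= lo
  fi(hi, ix$starts) - fi(lo - 0.5, ix$ends)
}

# Positions in [from, to] where point coverage n(p) can change: fragment
# extent starts and ends+1, clipped. Always includes `from`.
coverageChangePoints <- function(cov, chrom, from, to) {
  ix <- cov$ranges[[chrom]]
  if (is.null(ix) || length(ix$starts) == 0) return(from)
  s <- ix$starts; e <- ix$ends
  i1 <- fi(from - 0.5, s) + 1  # first start >= from
  i2 <- fi(to, s)              # last start <= to
  j1 <- fi(from - 1.5, e) + 1  # first end with end+1 >= from
  j2 <- fi(to - 1, e)          # last end with end+1 <= to
  cp <- c(from,
          if (i1 <= i2) s[i1:i2],
          if (j1 <= j2) e[j1:j2] + 1)
  sort(unique(cp))
}
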