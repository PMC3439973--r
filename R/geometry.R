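# geometry module: Eq-11 breakend trapezoids, convex polygon intersection in
# the (a,b) breakend plane, and geometric clustering of discordant fragments.
#
# Polygons are intersections of half-planes A*a + B*b <= C with A,B in
# {0,+1,-1} and integer C: the fragment band and the signature bounding box.
# All vertex coordinates are then integers or half-integers, so double
# arithmetic is exact and comparisons use a fixed small tolerance.

GEOM_TOL <- 1e-6

makePolygon <- function(halfplanes, signature, chromA, chromB) {
  hp <- normalizeHalfplanes(halfplanes)
  v <- enumerateVertices(hp)
  new("BreakendPolygon", halfplanes = hp, vertices = v,
      signature = signature, chromA = chromA, chromB = chromB)
}

# one row per direction (A,B), keeping the tightest offset C
normalizeHalfplanes <- function(hp) {
  key <- paste(hp[, 1], hp[, 2])
  cmin <- tapply(hp[, 3], key, min)
  ab <- do.call(rbind, strsplit(names(cmin), " "))
  out <- cbind(A = as.numeric(ab[, 1]), B = as.numeric(ab[, 2]),
               C = as.numeric(cmin))
  rownames(out) <- NULL
  out
}

# All pairwise boundary-line intersections that satisfy every constraint,
# deduplicated and ordered counter-clockwise. Zero rows means empty.
enumerateVertices <- function(hp) {
  n <- nrow(hp)
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      det <- hp[i, 1] * hp[j, 2] - hp[j, 1] * hp[i, 2]
      if (abs(det) < GEOM_TOL) next
      a <- (hp[i, 3] * hp[j, 2] - hp[j, 3] * hp[i, 2]) / det
      b <- (hp[i, 1] * hp[j, 3] - hp[j, 1] * hp[i, 3]) / det
      if (all(hp[, 1] * a + hp[, 2] * b <= hp[, 3] + GEOM_TOL))
        pts <- rbind(pts, c(a, b))
    }
  }
  if (nrow(pts) == 0) return(matrix(numeric(0), ncol = 2))
  pts <- unique(round(pts / GEOM_TOL) * GEOM_TOL)
  pts <- matrix(pts, ncol = 2)
  if (nrow(pts) > 2) {
    ctr <- colMeans(pts)
    ord <- order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]))
    pts <- pts[ord, , drop = FALSE]
  }
  colnames(pts) <- c("a", "b")
  pts
}

#' Breakend trapezoid of a discordant fragment alignment
#'
#' The convex set of mated breakend pairs (a, b) satisfying
#' `Lmin <= sign(x)(a - x) + sign(y)(b - y) <= Lmax`, intersected with the
#' signature bounding box: the breakends lie on the breakpoint-proximal side
#' of each read, i.e. `sign(x) = +1` requires `a >= x` and `sign(x) = -1`
#' requires `a <= x` (likewise for b and y).
#'
#' @param x,y Breakpoint-proximal coordinates of the two reads (`x < y` on a
#'   shared chromosome).
#' @param signX,signY Strand signs (+1 for the plus strand).
#' @param stats A [LibraryStats-class] (uses `lmin`, `lmax`).
#' @param signature Discordant signature label carried on the polygon.
#' @param chromA,chromB Chromosomes of the two breakend axes.
#' @return A [BreakendPolygon-class] with at most 6 vertices.
#' @examples
#' st <- LibraryStats(100, 200, 150)
#' fragmentTrapezoid(1000, 2000, +1, -1, st)
#' @export
fragmentTrapezoid <- function(x, y, signX, signY, stats,
                              signature = "deletion",
                              chromA = "chr1", chromB = chromA) {
  if (stats@lmax < stats@lmin) stop("Lmax < Lmin")
  stopifnot(signX %in% c(-1, 1), signY %in% c(-1, 1))
  cc <- signX * x + signY * y
  hp <- rbind(
    c(signX, signY, stats@lmax + cc),     # sx*a + sy*b <= Lmax + sx*x + sy*y
    c(-signX, -signY, -(stats@lmin + cc)),
    c(-signX, 0, -signX * x),             # a on the proximal side of x
    c(0, -signY, -signY * y)              # b on the proximal side of y
  )
  makePolygon(hp, signature, chromA, chromB)
}

# Trapezoid from one row of the fragment-alignment table. The clustering
# path uses inner-span band bounds [Lmin - 2*readLength, Lmax - 2*readLength]:
# with breakpoint-proximal coordinates, a fragment of length L straddling the
# true adjacency satisfies sign(x)(a-x) + sign(y)(b-y) = L - 2*readLength, so
# these bounds are exactly the ones that keep the true breakend pair inside
# every supporter's trapezoid (and match the lambda_d derivation).
alignmentTrapezoid <- function(row, stats) {
  inner <- new("LibraryStats",
               lmin = stats@lmin - 2 * stats@readLength,
               lmax = stats@lmax - 2 * stats@readLength,
               lavg = stats@lavg - 2 * stats@readLength,
               readLength = stats@readLength,
               technology = stats@technology)
  fragmentTrapezoid(row$x, row$y, row$signX, row$signY, inner,
                    signature = row$signature,
                    chromA = row$chromX, chromB = row$chromY)
}

#' Test whether points lie inside a breakend polygon
#'
#' @param poly A [BreakendPolygon-class].
#' @param a,b Coordinate vectors in the breakend plane.
#' @return Logical vector.
#' @export
polygonContains <- function(poly, a, b) {
  hp <- poly@halfplanes
  ok <- rep(TRUE, length(a))
  for (i in seq_len(nrow(hp)))
    ok <- ok & (hp[i, 1] * a + hp[i, 2] * b <= hp[i, 3] + GEOM_TOL)
  ok
}

#' Exact intersection of two breakend polygons
#'
#' @param p1,p2 [BreakendPolygon-class] objects on the same chromosome pair
#'   and with the same signature.
#' @return The intersection polygon (empty, with zero vertices, when the
#'   inputs are disjoint).
#' @export
intersectPolygons <- function(p1, p2) {
  if (p1@signature != p2@signature)
    stop("cannot intersect polygons with different signatures")
  if (p1@chromA != p2@chromA || p1@chromB != p2@chromB)
    stop("cannot intersect polygons on different chromosome pairs")
  if (isEmpty(p1) || isEmpty(p2))
    return(new("BreakendPolygon",
               halfplanes = rbind(p1@halfplanes, p2@halfplanes),
               vertices = matrix(numeric(0), ncol = 2),
               signature = p1@signature, chromA = p1@chromA,
               chromB = p1@chromB))
  makePolygon(rbind(p1@halfplanes, p2@halfplanes), p1@signature,
              p1@chromA, p1@chromB)
}

polygonRangeA <- function(poly) range(poly@vertices[, 1])
polygonRangeB <- function(poly) range(poly@vertices[, 2])

#' Polygon area (shoelace)
#'
#' Degenerate segment or point polygons have zero area.
#'
#' @param poly A [BreakendPolygon-class].
#' @return Numeric area in the breakend plane.
#' @export
polygonArea <- function(poly) {
  v <- poly@vertices
  if (nrow(v) < 3) return(0)
  i2 <- c(seq(2, nrow(v)), 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' Cluster discordant fragment alignments by trapezoid intersection
#'
#' Within each (chromosome pair, signature) stratum, finds all maximal
#' fragment sets whose trapezoids have a non-empty common intersection. The
#' candidate's polygon is that intersection. A fragment alignment may appear
#' in several candidates when its trapezoid intersects several groups; the
#' ambiguity is resolved later by the mapping sampler.
#'
#' @param x An [SVFragments-class] with the partition filled (clusters only
#'   fragments of class `"discordant"`).
#' @param signatures Signatures to cluster; defaults to deletion and the two
#'   inversion signatures.
#' @param maxComponent Components larger than this fall back to a greedy
#'   largest-first decomposition instead of full maximal-set enumeration.
#' @param nodeBudget Budget of polygon-intersection tests for the maximal-set enumeration before falling back to the greedy decomposition.
#' @return An [SVCandidateSet-class].
#' @export
clusterDiscordants <- function(x, signatures = c("deletion", "inversionPlus",
                                                 "inversionMinus"),
                               maxComponent = 200, nodeBudget = 20000) {
  stopifnot(is(x, "SVFragments"))
  al <- x@alignments
  disc <- names(x@fragClass)[x@fragClass == "discordant"]
  al <- al[al$status == "discordant" & al$fragment %in% disc &
             al$signature %in% signatures, , drop = FALSE]
  if (nrow(al) == 0) return(new("SVCandidateSet", candidates = list()))
  stats <- x@stats
  # canonical order for order-independent output
  al <- al[order(al$chromX, al$chromY, al$signature, al$x, al$y,
                 al$fragment), , drop = FALSE]
  al$alnId <- sprintf("%s#%d", al$fragment,
                      stats::ave(seq_len(nrow(al)), al$fragment,
                                 FUN = seq_along))

  strata <- split(seq_len(nrow(al)),
                  paste(al$chromX, al$chromY, al$signature, sep = "\r"))
  cands <- list()
  for (idx in strata) {
    sub <- al[idx, , drop = FALSE]
    polys <- lapply(seq_len(nrow(sub)),
                    function(i) alignmentTrapezoid(sub[i, ], stats))
    ra <- t(vapply(polys, polygonRangeA, numeric(2)))
    rb <- t(vapply(polys, polygonRangeB, numeric(2)))
    # bounding-box prefilter, then exact polygon test
    ova <- IRanges::findOverlaps(
      IRanges::IRanges(floor(ra[, 1]), ceiling(ra[, 2])))
    qh <- S4Vectors::queryHits(ova); sh <- S4Vectors::subjectHits(ova)
    pair <- cbind(qh, sh)[qh < sh, , drop = FALSE]
    if (nrow(pair)) {
      okB <- rb[pair[, 1], 1] <= rb[pair[, 2], 2] + GEOM_TOL &
        rb[pair[, 2], 1] <= rb[pair[, 1], 2] + GEOM_TOL
      pair <- pair[okB, , drop = FALSE]
    }
    if (nrow(pair)) {
      okP <- vapply(seq_len(nrow(pair)), function(r) {
        !isEmpty(intersectPolygons(polys[[pair[r, 1]]], polys[[pair[r, 2]]]))
      }, logical(1))
      pair <- pair[okP, , drop = FALSE]
    }
    g <- igraph::make_empty_graph(n = nrow(sub), directed = FALSE)
    if (nrow(pair)) g <- igraph::add_edges(g, t(pair))
    comp <- igraph::components(g)
    adj <- lapply(seq_len(nrow(sub)), function(i) {
      sort(unique(c(pair[pair[, 1] == i, 2], pair[pair[, 2] == i, 1])))
    })
    for (cid in seq_len(comp$no)) {
      members <- sort(which(comp$membership == cid))
      sets <- maximalIntersectingSets(members, polys, adj,
                                      maxComponent, nodeBudget)
      for (s in sets) {
        poly <- Reduce(intersectPolygons, polys[s])
        v <- poly@vertices
        cands[[length(cands) + 1]] <- list(
          fragments = sort(unique(sub$fragment[s])),
          alnIds = sub$alnId[s],
          polygon = poly,
          signature = sub$signature[1],
          chromA = sub$chromX[1], chromB = sub$chromY[1],
          k = length(unique(sub$fragment[s])),
          amax = max(v[, 1]), bmin = min(v[, 2]),
          svtype = switch(sub$signature[1], deletion = "DEL",
                          inversionPlus = "INV", inversionMinus = "INV",
                          "BND"))
      }
    }
  }
  # deterministic ids ordered by location
  ord <- order(vapply(cands, function(cc) cc$chromA, character(1)),
               vapply(cands, function(cc) cc$amax, numeric(1)),
               vapply(cands, function(cc) cc$bmin, numeric(1)),
               vapply(cands, function(cc) cc$signature, character(1)))
  cands <- cands[ord]
  for (i in seq_along(cands)) cands[[i]]$id <- sprintf("sv%05d", i)
  new("SVCandidateSet", candidates = cands)
}

# All maximal subsets of `members` whose polygons have a non-empty common
# intersection. Fast path: the whole component. Otherwise a Bron-Kerbosch
# style recursion on the pairwise-intersection graph with a feasibility
# check on the running polygon; greedy largest-first fallback when the
# component or the recursion budget is exceeded.
maximalIntersectingSets <- function(members, polys, adj, maxComponent,
                                    nodeBudget) {
  if (length(members) == 1) return(list(members))
  whole <- Reduce(intersectPolygons, polys[members])
  if (!isEmpty(whole)) return(list(members))
  if (length(members) > maxComponent)
    return(greedySets(members, polys))
  results <- list()
  budget <- nodeBudget  # counts polygon-intersection tests
  overrun <- FALSE
  inter <- function(p, v) {
    budget <<- budget - 1
    if (budget < 0) overrun <<- TRUE
    intersectPolygons(p, polys[[v]])
  }
  rec <- function(S, poly, cand, excl) {
    if (overrun) return()
    if (length(cand) == 0) {
      if (length(excl) == 0) results[[length(results) + 1]] <<- S
      return()
    }
    for (v in cand) {
      if (overrun) return()
      polyV <- if (is.null(poly)) polys[[v]] else inter(poly, v)
      nb <- adj[[v]]
      candV <- intersect(setdiff(cand, v), nb)
      candV <- candV[vapply(candV, function(w)
        !isEmpty(inter(polyV, w)), logical(1))]
      exclV <- intersect(excl, nb)
      exclV <- exclV[vapply(exclV, function(w)
        !isEmpty(inter(polyV, w)), logical(1))]
      rec(c(S, v), polyV, candV, exclV)
      cand <- setdiff(cand, v)
      excl <- c(excl, v)
    }
  }
  rec(integer(0), NULL, members, integer(0))
  if (overrun) return(greedySets(members, polys))
  unique(lapply(results, sort))
}

# repeatedly peel off a feasible set built by scanning in coordinate order
greedySets <- function(members, polys) {
  out <- list()
  remaining <- members
  while (length(remaining)) {
    S <- remaining[1]
    poly <- polys[[remaining[1]]]
    for (v in remaining[-1]) {
      p2 <- intersectPolygons(poly, polys[[v]])
      if (!isEmpty(p2)) { S <- c(S, v); poly <- p2 }
    }
    out[[length(out) + 1]] <- sort(S)
    remaining <- setdiff(remaining, S)
  }
  out
}
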