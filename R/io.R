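# External interfaces: the documented alignment TSV, optional BAM input via
# Rsamtools, BED/BED-graph tracks, and BEDPE/VCF output of calls.

#' Read alignment records from the documented TSV
#'
#' Tab-separated with header: `fragment`, `read` (1/2), `chrom`, `pos`
#' (1-based leftmost aligned base), `strand`, `len`, `mapq`. One row per
#' read alignment; multi-mapped reads repeat rows.
#'
#' @param path File path.
#' @return Data.frame suitable for [pairReads()].
#' @export
readAlignmentTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(fragment = "character", chrom = "character",
                            strand = "character"))
}

#' Write alignment records to the documented TSV
#'
#' @param reads Data.frame as accepted by [pairReads()].
#' @param path File path.
#' @export
writeAlignmentTsv <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read paired alignments from a BAM file
#'
#' Convenience wrapper over Rsamtools (suggested dependency): extracts
#' mapped, paired primary alignments and reshapes them into the read-level
#' table accepted by [pairReads()].
#'
#' @param path BAM path.
#' @param chrom Optional chromosome restriction.
#' @return Data.frame for [pairReads()].
#' @export
readAlignmentBam <- function(path, chrom = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("readAlignmentBam requires the Rsamtools package")
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "pos", "strand", "qwidth", "mapq")
  param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  firstOfPair <- bitwAnd(b$flag, 64L) > 0
  out <- data.frame(
    fragment = b$qname, read = ifelse(firstOfPair, 1L, 2L),
    chrom = as.character(b$rname), pos = b$pos,
    strand = as.character(b$strand), len = b$qwidth,
    mapq = ifelse(is.na(b$mapq), 0L, b$mapq), stringsAsFactors = FALSE)
  if (!is.null(chrom)) out <- out[out$chrom %in% chrom, , drop = FALSE]
  out[!is.na(out$pos), , drop = FALSE]
}

#' Read a mapability track (BED-graph or BED)
#'
#' BED-graph columns chrom/start/end/value with 0-based half-open
#' coordinates are converted to the package's 1-based closed convention.
#' A 3-column BED is read as value-1 intervals.
#'
#' @param path File path.
#' @return Data.frame with `chrom`, `start`, `end`, `value`.
#' @export
readMapabilityBed <- function(path) {
  tr <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(tr)[1:3] <- c("chrom", "start", "end")
  tr$value <- if (ncol(tr) >= 4) as.numeric(tr[[4]]) else 1
  data.frame(chrom = tr$chrom, start = tr$start + 1, end = tr$end,
             value = tr$value, stringsAsFactors = FALSE)
}

#' Write discordant fragment alignments as BEDPE
#'
#' @param x An [SVFragments-class].
#' @param path Output path.
#' @export
writeDiscordantBedpe <- function(x, path) {
  al <- fragmentAlignments(x)
  al <- al[al$status == "discordant", , drop = FALSE]
  df <- data.frame(
    chrom1 = al$chromX, start1 = al$posX - 1, end1 = al$posX + al$lenX - 1,
    chrom2 = al$chromY, start2 = al$posY - 1, end2 = al$posY + al$lenY - 1,
    name = al$fragment, score = al$mapq,
    strand1 = al$strandX, strand2 = al$strandY,
    signature = al$signature)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Write candidate clusters as a TSV
#'
#' One row per candidate: id, chromosome pair, signature, support count,
#' supporting fragment ids, and the polygon vertex list.
#'
#' @param cands An [SVCandidateSet-class].
#' @param path Output path.
#' @export
writeClusterTsv <- function(cands, path) {
  rows <- lapply(candidates(cands), function(cc) {
    v <- breakendVertices(cc$polygon)
    data.frame(id = cc$id, chromA = cc$chromA, chromB = cc$chromB,
               signature = cc$signature, k = cc$k,
               fragments = paste(cc$fragments, collapse = ","),
               vertices = paste(sprintf("%g:%g", v[, 1], v[, 2]),
                                collapse = ";"))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Write final calls as BEDPE
#'
#' Score column carries `log Lambda`; the genotype column the copy call.
#'
#' @param calls An [SVCalls-class].
#' @param path Output path.
#' @export
writeCallsBedpe <- function(calls, path) {
  df <- svCallTable(calls)
  out <- data.frame(
    chrom1 = df$chromA, start1 = df$start - 1, end1 = df$start,
    chrom2 = df$chromB, start2 = df$end - 1, end2 = df$end,
    name = df$id, score = sprintf("%.4f", df$logLambda),
    strand1 = ".", strand2 = ".",
    svtype = df$svtype,
    genotype = ifelse(df$chat == 2, "1/1",
                      ifelse(df$chat == 1, "0/1", "0/0")),
    support = df$support)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Write final calls as VCF 4.1
#'
#' Uses `SVTYPE=DEL`/`INV` symbolic alleles with `END`, and `CIPOS`/`CIEND`
#' confidence intervals taken from the breakend polygon extent around the
#' maximum-likelihood breakend pair.
#'
#' @param calls An [SVCalls-class].
#' @param cands The [SVCandidateSet-class] the calls came from (for polygon
#'   extents).
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @export
writeCallsVcf <- function(calls, cands, path, sample = "SAMPLE") {
  df <- svCallTable(calls)
  byId <- setNames(candidates(cands),
                   vapply(candidates(cands), function(cc) cc$id,
                          character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##source=svprob",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    paste0("##INFO=<ID=CIPOS,Number=2,Type=Integer,",
           "Description=\"Confidence interval around POS\">"),
    paste0("##INFO=<ID=CIEND,Number=2,Type=Integer,",
           "Description=\"Confidence interval around END\">"),
    paste0("##INFO=<ID=SUPPORT,Number=1,Type=Integer,",
           "Description=\"Supporting discordant fragments\">"),
    paste0("##INFO=<ID=LOGLR,Number=1,Type=Float,",
           "Description=\"Log likelihood ratio\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")), con)
  for (i in seq_len(nrow(df))) {
    cc <- byId[[df$id[i]]]
    v <- breakendVertices(cc$polygon)
    pos <- round(df$bestA[i]); endp <- round(df$bestB[i])
    cipos <- c(floor(min(v[, 1])) - pos, ceiling(max(v[, 1])) - pos)
    ciend <- c(floor(min(v[, 2])) - endp, ceiling(max(v[, 2])) - endp)
    gt <- if (df$chat[i] == 2) "1/1" else if (df$chat[i] == 1) "0/1"
          else "0/0"
    info <- sprintf("SVTYPE=%s;END=%d;CIPOS=%d,%d;CIEND=%d,%d;SUPPORT=%d;LOGLR=%.4f",
                    df$svtype[i], endp, cipos[1], cipos[2], ciend[1],
                    ciend[2], df$support[i], df$logLambda[i])
    writeLines(paste(df$chromA[i], pos, df$id[i], "N",
                     paste0("<", df$svtype[i], ">"), ".", "PASS", info,
                     "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}

#' Write library statistics as TSV
#'
#' @param stats A [LibraryStats-class].
#' @param path Output path.
#' @export
writeLibraryStatsTsv <- function(stats, path) {
  df <- data.frame(lmin = stats@lmin, lmax = stats@lmax, lavg = stats@lavg,
                   readLength = stats@readLength,
                   technology = stats@technology)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
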