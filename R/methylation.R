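## Cytosine context assignment, cytosine-report I/O, replicate pooling and
## the genome-scale methylation summaries.

## context of cytosines given a chromosome as a character vector, positions
## and strand; returns NA where the base is not a C on that strand or the
## two-base downstream window runs off the chromosome end.
.contextAt <- function(chars, pos, strandChar) {
  L <- length(chars)
  ctx <- rep(NA_character_, length(pos))
  if (strandChar == "+") {
    isC <- chars[pos] == "C"
    n1 <- ifelse(pos + 1L <= L, chars[pmin(pos + 1L, L)], NA)
    n2 <- ifelse(pos + 2L <= L, chars[pmin(pos + 2L, L)], NA)
    ctx[isC & !is.na(n1) & n1 == "G"] <- "CG"
    rest <- isC & !is.na(n1) & n1 != "G" & !is.na(n2)
    ctx[rest & n2 == "G"] <- "CHG"
    ctx[rest & n2 != "G"] <- "CHH"
  } else {
    ## on the minus strand the cytosine sits opposite a forward G; its
    ## downstream bases are the complements of forward pos-1, pos-2
    isC <- chars[pos] == "G"
    n1 <- ifelse(pos - 1L >= 1L, chars[pmax(pos - 1L, 1L)], NA)
    n2 <- ifelse(pos - 2L >= 1L, chars[pmax(pos - 2L, 1L)], NA)
    ctx[isC & !is.na(n1) & n1 == "C"] <- "CG"
    rest <- isC & !is.na(n1) & n1 != "C" & !is.na(n2)
    ctx[rest & n2 == "C"] <- "CHG"
    ctx[rest & n2 != "C"] <- "CHH"
  }
  ctx
}

#' Assign the methylation context of a cytosine
#'
#' Reads the two bases downstream of the cytosine in strand orientation:
#' \code{CG} if the next base is G, \code{CHG} if the base after next is G,
#' \code{CHH} otherwise (H = A, C or T).  On the minus strand the forward
#' base at \code{position} must be a G (the paired cytosine).
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param chrom chromosome name.
#' @param position 1-based forward-strand position (vectorised).
#' @param strand \code{"+"} or \code{"-"}.
#' @return \code{"CG"}, \code{"CHG"}, \code{"CHH"}, or \code{NA} when the
#'   base is not a cytosine on that strand or the downstream window exceeds
#'   the chromosome end.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' assignContext(g, "chr1", 2, "+")  # "CG"
#' @export
assignContext <- function(genome, chrom, position, strand) {
  stopifnot(is(genome, "DNAStringSet"), chrom %in% names(genome))
  strand <- match.arg(strand, c("+", "-"))
  chars <- strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
  if (any(position < 1L) || any(position > length(chars)))
    stop("position out of chromosome range")
  .contextAt(chars, as.integer(position), strand)
}

#' Locate every cytosine of a genome with its context
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param regions optional GRanges; only cytosines within these intervals are
#'   returned (e.g. the reduced representation genome).
#' @return GRanges of width-1 cytosine positions on both strands with a
#'   \code{context} metadata column.
#' @export
findCytosines <- function(genome, regions = NULL) {
  stopifnot(is(genome, "DNAStringSet"))
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  out <- lapply(names(genome), function(chromName) {
    chars <- strsplit(as.character(genome[[chromName]]), "", fixed = TRUE)[[1]]
    res <- list()
    for (st in c("+", "-")) {
      pos <- if (st == "+") which(chars == "C") else which(chars == "G")
      if (!length(pos)) next
      ctx <- .contextAt(chars, pos, st)
      keep <- !is.na(ctx)
      if (!any(keep)) next
      res[[st]] <- GRanges(chromName, IRanges(pos[keep], width = 1L),
                           strand = st, context = ctx[keep])
    }
    if (length(res)) do.call(c, unname(res)) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  gr <- if (length(out)) sort(do.call(c, out), ignore.strand = TRUE)
        else GRanges(context = character())
  seqlevels(gr) <- names(genome)
  seqlengths(gr) <- width(genome)
  if (!is.null(regions))
    gr <- gr[overlapsAny(gr, regions, ignore.strand = TRUE)]
  gr
}

#' Read / write a per-cytosine methylation report
#'
#' Tab-separated columns: chrom, 1-based position, strand, context,
#' methylated_count, total_count, sample_id.  Header lines starting with
#' \code{#} are tolerated on input.
#'
#' @param path file path.
#' @return \code{readCytosineReport} returns a GRanges with metadata columns
#'   \code{context}, \code{methylated}, \code{total}, \code{sample_id}.
#' @export
readCytosineReport <- function(path) {
  top <- readLines(path, n = 100L, warn = FALSE)
  nskip <- sum(cumprod(startsWith(top, "#")))
  dt <- fread(path, sep = "\t", header = FALSE, skip = nskip,
              col.names = c("chrom", "position", "strand", "context",
                            "methylated_count", "total_count", "sample_id"))
  ## files without a commented header: drop a literal header row if present
  if (nrow(dt) && identical(dt$chrom[1], "chrom")) dt <- dt[-1]
  GRanges(dt$chrom, IRanges(as.integer(dt$position), width = 1L),
          strand = dt$strand, context = dt$context,
          methylated = as.integer(dt$methylated_count),
          total = as.integer(dt$total_count),
          sample_id = dt$sample_id)
}

#' @param records GRanges as returned by \code{readCytosineReport} or the
#'   simulator.
#' @rdname readCytosineReport
#' @export
writeCytosineReport <- function(records, path) {
  dt <- data.table(
    chrom = as.character(seqnames(records)),
    position = start(records),
    strand = as.character(strand(records)),
    context = records$context,
    methylated_count = records$methylated,
    total_count = records$total,
    sample_id = if (!is.null(records$sample_id)) records$sample_id else "sample")
  header <- paste0("#", paste(names(dt), collapse = "\t"))
  writeLines(header, path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

.recordsToDT <- function(gr) {
  data.table(chrom = as.character(seqnames(gr)), position = start(gr),
             strand. = as.character(strand(gr)), context = gr$context,
             methylated = as.integer(gr$methylated),
             total = as.integer(gr$total))
}

#' Pool replicate cytosine counts into one condition
#'
#' Sums methylated and total read counts cytosine-by-cytosine across the
#' replicates of one condition; cytosines absent from a replicate contribute
#' zero.  Conflicting context annotations at one position are treated as
#' corrupt input.
#'
#' @param replicates a list of cytosine-record GRanges (one per replicate) or
#'   a single GRanges covering all replicates.
#' @param condition condition label.
#' @return A \linkS4class{PooledCondition}.
#' @export
poolReplicates <- function(replicates, condition = "condition") {
  if (is(replicates, "GRanges")) replicates <- list(replicates)
  stopifnot(length(replicates) >= 1L)
  sl <- seqlengths(replicates[[1]])
  dt <- rbindlist(lapply(replicates, .recordsToDT))
  ## context joins the grouping key: a position appearing under two contexts
  ## then yields duplicate (chrom, position, strand) rows -> corrupt input
  pooled <- dt[, list(methylated = sum(methylated), total = sum(total)),
               by = c("chrom", "position", "strand.", "context")]
  dup <- duplicated(pooled[, c("chrom", "position", "strand.")])
  if (any(dup))
    stop("conflicting context annotations at ", sum(dup),
         " position(s): corrupt input")
  setorder(pooled, chrom, position, strand.)
  gr <- GRanges(pooled$chrom, IRanges(pooled$position, width = 1L),
                strand = pooled$strand., context = pooled$context,
                methylated = pooled$methylated, total = pooled$total)
  if (length(sl) && !anyNA(sl)) {
    seqlevels(gr) <- names(sl)
    seqlengths(gr) <- sl
  }
  new("PooledCondition", sites = gr, condition = condition)
}

.pooledSites <- function(x) {
  if (is(x, "PooledCondition")) sites(x) else x
}

#' Genome-wide methylation level of one context
#'
#' The count-weighted level: summed methylated reads over summed total reads
#' across all cytosines of the context with at least \code{minReads}
#' coverage.  The unweighted mean of per-cytosine proportions is exposed as
#' an option (\code{weighted = FALSE}); the count-weighted form is the
#' default because it is robust to uneven coverage.
#'
#' @param pooled a \linkS4class{PooledCondition} (or cytosine GRanges).
#' @param context \code{"CG"}, \code{"CHG"} or \code{"CHH"}.
#' @param minReads minimum total reads for a cytosine to qualify.
#' @param weighted count-weighted (default) or unweighted mean.
#' @return A proportion in [0, 1].
#' @export
globalContextLevel <- function(pooled, context, minReads = 1L,
                               weighted = TRUE) {
  .checkContext(context)
  gr <- .pooledSites(pooled)
  gr <- gr[gr$context == context & gr$total >= minReads]
  if (!length(gr)) stop("no qualifying cytosines for context ", context)
  if (weighted) sum(gr$methylated) / sum(gr$total)
  else mean(gr$methylated / gr$total)
}

#' Binned chromosome methylation profile
#'
#' Count-weighted methylation level per consecutive fixed-width bin along
#' each chromosome (5 Mb by default, the scale used for low-resolution
#' chromosome profiles).  Bins without any covered cytosine are reported as
#' \code{NA}, not 0.
#'
#' @inheritParams globalContextLevel
#' @param bin bin width in bp.
#' @return data.frame with chrom, bin start/end and level.
#' @export
chromosomeProfile <- function(pooled, context, bin = 5e6) {
  .checkContext(context)
  stopifnot(bin > 0)
  gr <- .pooledSites(pooled)
  gr <- gr[gr$context == context & gr$total > 0]
  if (!length(gr))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), level = numeric()))
  dt <- data.table(chrom = as.character(seqnames(gr)), position = start(gr),
                   methylated = gr$methylated, total = gr$total)
  dt[, binIndex := (position - 1L) %/% bin]
  lev <- dt[, list(level = sum(methylated) / sum(total)), by = c("chrom", "binIndex")]
  sl <- seqlengths(gr)
  out <- rbindlist(lapply(unique(lev$chrom), function(ch) {
    maxPos <- if (length(sl) && !is.na(sl[ch])) sl[ch]
              else max(dt[chrom == ch, position])
    idx <- 0:((maxPos - 1) %/% bin)
    grid <- data.table(chrom = ch, binIndex = idx)
    merge(grid, lev[lev$chrom == ch], by = c("chrom", "binIndex"),
          all.x = TRUE)
  }))
  data.frame(chrom = out$chrom, start = out$binIndex * bin + 1,
             end = (out$binIndex + 1) * bin, level = out$level)
}

#' Share of each context among methylated cytosines
#'
#' A cytosine is called methylated when its level (methylated/total) is at
#' least \code{callThreshold}.  Shares are methylated-cytosine counts per
#' context over all methylated cytosines and sum to 1.
#'
#' @inheritParams globalContextLevel
#' @param callThreshold level at or above which a cytosine is called
#'   methylated.
#' @return Named numeric of length 3 (CG, CHG, CHH) summing to 1.
#' @export
contextShare <- function(pooled, callThreshold = 0.5) {
  gr <- .pooledSites(pooled)
  gr <- gr[gr$total > 0]
  called <- gr[gr$methylated / gr$total >= callThreshold]
  if (!length(called)) stop("no methylated cytosines at threshold ",
                            callThreshold)
  counts <- table(factor(called$context, levels = c("CG", "CHG", "CHH")))
  setNames(as.numeric(counts) / sum(counts), c("CG", "CHG", "CHH"))
}

#' Bisulfite conversion rate from an unmethylated control
#'
#' With a truly unmethylated control sequence, every methylated call is a
#' conversion failure, so rate = 1 - (summed methylated / summed total).
#'
#' @param records cytosine GRanges (or \linkS4class{PooledCondition}) from
#'   the unmethylated control.
#' @return Conversion rate in [0, 1].
#' @export
conversionRate <- function(records) {
  gr <- .pooledSites(records)
  tot <- sum(as.numeric(gr$total))
  if (tot == 0) stop("no reads in conversion control")
  1 - sum(as.numeric(gr$methylated)) / tot
}
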