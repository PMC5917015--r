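## In-silico restriction digestion and size selection: the reduced
## representation genome (RRG) is the interval universe within which RRBS
## observes methylation.

#' Virtually digest a genome with a restriction enzyme
#'
#' Scans the forward strand of each chromosome for the (palindromic)
#' recognition site and cuts after \code{cutOffset} bases of every
#' occurrence, the MspI C^CGG convention by default.  The returned fragments
#' tile each chromosome exactly: they are disjoint, gap-free and their
#' concatenation reconstructs the sequence.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} (named chromosomes).
#' @param site recognition site, default \code{"CCGG"} (MspI).
#' @param cutOffset cut placed after this many bases of each site occurrence.
#' @return GRanges of fragments (1-based inclusive) carrying seqlengths.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTTCCGGAA"))
#' digestGenome(g)  # fragments 1-3, 4-9, 10-14
#' @export
digestGenome <- function(genome, site = "CCGG", cutOffset = 1L) {
  stopifnot(is(genome, "DNAStringSet"))
  if (length(genome) == 0L) return(GRanges())
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  lens <- width(genome)
  frags <- lapply(seq_along(genome), function(i) {
    L <- lens[i]
    if (L == 0L) return(NULL)
    hits <- matchPattern(DNAString(site), genome[[i]])
    cuts <- start(hits) + cutOffset - 1L
    cuts <- sort(unique(cuts[cuts >= 1L & cuts <= L - 1L]))
    data.frame(chrom = names(genome)[i],
               start = c(1L, cuts + 1L), end = c(cuts, L))
  })
  df <- do.call(rbind, frags)
  gr <- if (is.null(df)) GRanges()
        else GRanges(df$chrom, IRanges(df$start, df$end))
  seqlevels(gr) <- names(genome)
  seqlengths(gr) <- lens
  gr
}

#' Size-select digestion fragments
#'
#' Retains fragments whose length lies in \code{[minLen, maxLen]} (both ends
#' inclusive).  Two dialects are first-class: the sequencing-library window
#' (40-220 bp) and the broader virtual-reference window (20-400 bp) used when
#' reducing the reference genome, which deliberately tolerates imprecise
#' physical size selection.
#'
#' @param fragments GRanges of digestion fragments (from
#'   \code{\link{digestGenome}}).
#' @param minLen,maxLen inclusive length bounds in bp; ignored when
#'   \code{preset} is given.
#' @param preset \code{"library"} (40-220) or \code{"virtual-reference"}
#'   (20-400).
#' @return An \linkS4class{RRGIntervalSet}.  \code{genomeFraction} is
#'   retained bases over the genome size (\code{NA} with a warning when the
#'   fragments carry no seqlengths).
#' @export
sizeSelect <- function(fragments, minLen = 20L, maxLen = 400L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("library", "virtual-reference"))
    if (preset == "library") { minLen <- 40L; maxLen <- 220L }
    else { minLen <- 20L; maxLen <- 400L }
  }
  if (minLen <= 0L || minLen > maxLen)
    stop("size selection requires 0 < minLen <= maxLen")
  keep <- fragments[width(fragments) >= minLen & width(fragments) <= maxLen]
  total <- sum(as.numeric(width(keep)))
  sl <- seqlengths(keep)
  if (length(sl) && !anyNA(sl)) {
    frac <- total / sum(as.numeric(sl))
  } else {
    warning("fragments carry no seqlengths; genomeFraction is NA")
    frac <- NA_real_
  }
  new("RRGIntervalSet", intervals = keep, totalBases = total,
      genomeFraction = frac)
}

#' Bases of each feature covered by the reduced representation genome
#'
#' For each feature, the number of its bases lying in the union of retained
#' RRG intervals (union, not a per-fragment sum, so overlapping intervals are
#' not double counted).
#'
#' @param rrg an \linkS4class{RRGIntervalSet} or GRanges.
#' @param features GRanges of features; if a \code{gene_id} or \code{te_id}
#'   column is present the result is named by it.
#' @return Integer vector of covered bases, one per feature (never exceeding
#'   the feature length).  Features on chromosomes absent from the RRG get 0
#'   with a warning.
#' @export
featureCoverage <- function(rrg, features) {
  ivs <- if (is(rrg, "RRGIntervalSet")) rrgRanges(rrg) else rrg
  red <- reduce(ivs, ignore.strand = TRUE)
  missing <- !as.character(seqnames(features)) %in%
    as.character(seqnames(red))
  if (any(missing))
    warning(sum(missing), " feature(s) on chromosomes absent from the RRG; ",
            "covered bases set to 0")
  common <- union(seqlevels(features), seqlevels(red))
  seqlevels(red) <- common
  features2 <- features
  seqlevels(features2) <- common
  hits <- findOverlaps(features2, red, ignore.strand = TRUE)
  cov <- integer(length(features))
  if (length(hits)) {
    ov <- width(pintersect(ranges(features)[queryHits(hits)],
                           ranges(red)[subjectHits(hits)]))
    agg <- rowsum(ov, queryHits(hits))
    cov[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  }
  ids <- if (!is.null(features$gene_id)) features$gene_id
         else if (!is.null(features$te_id)) features$te_id
  if (!is.null(ids)) names(cov) <- ids
  cov
}
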