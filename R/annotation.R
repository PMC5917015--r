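## Promoter derivation, DMR-to-feature classification and nearest-gene
## assignment for transposable elements.

#' Derive promoter intervals from stranded genes
#'
#' The promoter is the \code{upstream} bases (2000 by default) immediately
#' 5' of the gene: for a + strand gene [s, e] the interval [s - upstream,
#' s - 1]; for a - strand gene the interval [e + 1, e + upstream].
#' Promoters are truncated at chromosome bounds and abut their gene.
#'
#' @param genes stranded GRanges with a \code{gene_id} column; seqlengths
#'   are used for truncation at the right chromosome edge.
#' @param upstream promoter length in bp.
#' @return GRanges of promoters carrying the parent \code{gene_id}.
#' @export
buildPromoters <- function(genes, upstream = 2000L) {
  if (length(genes) == 0L)
    return(GRanges(gene_id = character()))
  if (any(strand(genes) == "*"))
    stop("genes must be stranded to derive promoters")
  plus <- as.logical(strand(genes) == "+")
  pstart <- ifelse(plus, start(genes) - upstream, end(genes) + 1L)
  pend <- ifelse(plus, start(genes) - 1L, end(genes) + upstream)
  pstart <- pmax(pstart, 1L)
  sl <- seqlengths(genes)
  if (length(sl) && !anyNA(sl))
    pend <- pmin(pend, sl[as.character(seqnames(genes))])
  keep <- pend >= pstart
  if (!all(keep))
    warning(sum(!keep), " gene(s) yielded empty promoters at chromosome edges")
  gr <- GRanges(seqnames(genes)[keep], IRanges(pstart[keep], pend[keep]),
                strand = strand(genes)[keep],
                gene_id = genes$gene_id[keep])
  if (length(sl) && !anyNA(sl)) {
    seqlevels(gr) <- seqlevels(genes)
    seqlengths(gr) <- sl
  }
  gr
}

#' Build a FeatureSet from genes and TEs
#'
#' @param genes stranded GRanges with \code{gene_id}.
#' @param tes GRanges of transposable elements; a \code{te_id} column is
#'   added when absent.
#' @param upstream promoter length passed to \code{\link{buildPromoters}}.
#' @return A \linkS4class{FeatureSet}.
#' @export
featureSet <- function(genes, tes = GRanges(), upstream = 2000L) {
  if (length(tes) && is.null(tes$te_id))
    tes$te_id <- paste0("te", seq_along(tes))
  new("FeatureSet", genes = genes, tes = tes,
      promoters = buildPromoters(genes, upstream))
}

#' Classify DMRs by the genome feature they fall in
#'
#' Each DMR receives exactly one class by precedence: overlaps a gene and
#' that same gene's promoter -> \code{"gene+promoter"}; else overlaps any TE
#' -> \code{"TE"}; else a gene -> \code{"gene"}; else a promoter ->
#' \code{"promoter"}; else \code{"intergenic"}.  Overlap means at least one
#' shared base.  TE takes precedence over gene because in TE-rich genomes
#' most differential methylation is TE-resident, often nested inside genes.
#'
#' @param dmrs GRanges of DMRs.
#' @param features a \linkS4class{FeatureSet}.
#' @return data.frame with one row per DMR: \code{class} and the
#'   comma-separated \code{featureIds} overlapped by the winning class.
#' @export
classifyDMRs <- function(dmrs, features) {
  stopifnot(is(features, "FeatureSet"))
  n <- length(dmrs)
  og <- findOverlaps(dmrs, genes(features), ignore.strand = TRUE)
  op <- findOverlaps(dmrs, promoters2k(features), ignore.strand = TRUE)
  ot <- findOverlaps(dmrs, tes(features), ignore.strand = TRUE)
  geneIds <- split(genes(features)$gene_id[subjectHits(og)],
                   factor(queryHits(og), levels = seq_len(n)))
  promIds <- split(promoters2k(features)$gene_id[subjectHits(op)],
                   factor(queryHits(op), levels = seq_len(n)))
  teIds <- split(tes(features)$te_id[subjectHits(ot)],
                 factor(queryHits(ot), levels = seq_len(n)))
  cls <- character(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    g <- geneIds[[i]]; p <- promIds[[i]]; t <- teIds[[i]]
    both <- intersect(g, p)
    if (length(both)) {
      cls[i] <- "gene+promoter"; ids[i] <- paste(both, collapse = ",")
    } else if (length(t)) {
      cls[i] <- "TE"; ids[i] <- paste(t, collapse = ",")
    } else if (length(g)) {
      cls[i] <- "gene"; ids[i] <- paste(g, collapse = ",")
    } else if (length(p)) {
      cls[i] <- "promoter"; ids[i] <- paste(p, collapse = ",")
    } else {
      cls[i] <- "intergenic"; ids[i] <- ""
    }
  }
  data.frame(class = cls, featureIds = ids)
}

#' Percentage share of DMRs per feature class
#'
#' @param classifications data.frame from \code{\link{classifyDMRs}}.
#' @return Named numeric over the five classes (TE, gene, promoter,
#'   gene+promoter, intergenic), in percent, summing to 100.
#' @export
featureShare <- function(classifications) {
  if (!nrow(classifications)) stop("no DMRs to summarise")
  lv <- c("TE", "gene", "promoter", "gene+promoter", "intergenic")
  counts <- table(factor(classifications$class, levels = lv))
  setNames(100 * as.numeric(counts) / sum(counts), lv)
}

#' Closest gene to each transposable element
#'
#' Distance is 0 for an overlapping gene, otherwise the number of bases
#' strictly between the two intervals.  Ties are broken by the smaller gene
#' start coordinate.  The sign marks orientation in forward coordinates:
#' negative when the gene lies upstream (left) of the TE.
#'
#' @param te GRanges of TEs (vectorised).
#' @param genes GRanges of genes with \code{gene_id}.
#' @return data.frame per TE: \code{te_id}, \code{gene_id}, signed
#'   \code{distance} (NA with a warning when the TE's chromosome has no
#'   gene).
#' @export
closestGene <- function(te, genes) {
  teIds <- if (!is.null(te$te_id)) te$te_id else paste0("te", seq_along(te))
  out <- data.frame(te_id = teIds, gene_id = NA_character_,
                    distance = NA_real_)
  noGene <- 0L
  for (i in seq_along(te)) {
    onChrom <- which(as.character(seqnames(genes)) ==
                     as.character(seqnames(te))[i])
    if (!length(onChrom)) { noGene <- noGene + 1L; next }
    g <- genes[onChrom]
    gap <- ifelse(end(g) < start(te)[i], start(te)[i] - end(g) - 1L,
           ifelse(start(g) > end(te)[i], start(g) - end(te)[i] - 1L, 0L))
    best <- onChrom[order(gap, start(g))][1L]
    bi <- match(best, onChrom)
    sgn <- if (gap[bi] == 0) 1 else if (end(g)[bi] < start(te)[i]) -1 else 1
    out$gene_id[i] <- genes$gene_id[best]
    out$distance[i] <- sgn * gap[bi]
  }
  if (noGene > 0L)
    warning(noGene, " TE(s) on chromosomes without genes: closest gene NA")
  out
}
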