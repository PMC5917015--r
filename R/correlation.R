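## Methylome-transcriptome linkage: coverage gating, 2x2 contingency
## construction, the exact Fisher test and scatter data.

#' Gate features on reduced-representation coverage
#'
#' Genes enter the contingency universe only when the RRG covers at least
#' \code{minCovered} of their bases (500 bp by default, a compromise between
#' discarding genes with DMRs and keeping genes without methylation
#' information).  TEs are gated at any coverage (\code{minCovered = 1}),
#' because many TEs are short.
#'
#' @param coverage named integer vector of covered bases per feature (from
#'   \code{\link{featureCoverage}}).
#' @param minCovered inclusive minimum covered bases.
#' @return Character vector of eligible feature ids.
#' @export
gateGenes <- function(coverage, minCovered = 500L) {
  if (is.null(names(coverage)))
    stop("coverage must be named by feature id")
  names(coverage)[coverage >= minCovered]
}

#' Build the 2x2 methylation-expression contingency table
#'
#' Cells over the eligible universe: a = differentially methylated and
#' expressed, b = only methylated, c = only expressed, d = neither.
#' Members of \code{dmSet} or \code{deSet} outside the universe are dropped
#' with a message.
#'
#' @param eligible character vector, the gated feature universe.
#' @param dmSet ids called differentially methylated.
#' @param deSet ids called differentially expressed.
#' @return A \linkS4class{ContingencyTable2x2}.
#' @export
buildContingency <- function(eligible, dmSet, deSet) {
  eligible <- unique(eligible)
  if (!length(eligible)) stop("empty eligible universe")
  dropped <- sum(!unique(dmSet) %in% eligible) +
    sum(!unique(deSet) %in% eligible)
  if (dropped > 0)
    message(dropped, " feature(s) outside the gated universe dropped")
  dm <- eligible %in% dmSet
  de <- eligible %in% deSet
  new("ContingencyTable2x2",
      a = sum(dm & de), b = sum(dm & !de),
      c = sum(!dm & de), d = sum(!dm & !de))
}

.fisherP <- function(a, b, c, d, relTol = 1e-7) {
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("zero margin: no association testable, p = 1")
    return(1)
  }
  m <- a + b          # margin of row 1
  n <- c + d
  k <- a + c          # margin of column 1
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  pObs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= pObs * (1 + relTol)])
  min(p, 1)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with the point-probability rule: the p-value
#' sums the probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table (with a
#' small relative tolerance on the comparison to absorb floating-point
#' error).  A zero margin yields p = 1 with a warning.
#'
#' @param table a \linkS4class{ContingencyTable2x2}, or the cell \code{a}
#'   when the four cells are given individually.
#' @param b,c,d remaining cells when given individually.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisherExactTest(5, 0, 0, 5)  # 2/252
#' @export
fisherExactTest <- function(table, b, c, d) {
  if (is(table, "ContingencyTable2x2"))
    .fisherP(table@a, table@b, table@c, table@d)
  else .fisherP(table, b, c, d)
}

#' Whole-number percentage of DM genes that are also DE
#'
#' @param nDmDe genes both differentially methylated and expressed.
#' @param nDm genes differentially methylated (> 0).
#' @return Integer percent, rounded half away from zero.
#' @examples
#' dmDePercentage(41, 253)  # 16
#' dmDePercentage(7, 37)    # 19
#' @export
dmDePercentage <- function(nDmDe, nDm) {
  if (nDm <= 0) stop("nDm must be positive")
  if (nDmDe > nDm) stop("nDmDe cannot exceed nDm")
  as.integer(roundHalfUp(100 * nDmDe / nDm))
}

#' Methylation-difference vs expression scatter data for TE DMRs
#'
#' One point per TE-resident DMR whose TE's closest gene has a defined,
#' finite log2 fold change: x = the DMR's methylation proportion difference,
#' y = the gene's log2 fold change.  By default only significant DEGs are
#' kept; \code{significantOnly = FALSE} gives the all-genes variant.
#'
#' @param dmrs GRanges of DMRs (with a \code{diff} column).
#' @param features a \linkS4class{FeatureSet}.
#' @param expression expression data.frame.
#' @param significantOnly restrict to significant DEGs.
#' @return data.frame: te_id, gene_id, methDiff, log2fc.
#' @export
scatterData <- function(dmrs, features, expression, significantOnly = TRUE) {
  empty <- data.frame(te_id = character(), gene_id = character(),
                      methDiff = numeric(), log2fc = numeric())
  if (!length(dmrs)) return(empty)
  ot <- findOverlaps(dmrs, tes(features), ignore.strand = TRUE)
  if (!length(ot)) return(empty)
  ## one TE per DMR: the one sharing most bases
  ovw <- width(pintersect(ranges(dmrs)[queryHits(ot)],
                          ranges(tes(features))[subjectHits(ot)]))
  best <- vapply(split(seq_along(ovw), queryHits(ot)),
                 function(i) i[which.max(ovw[i])], integer(1))
  teIdx <- subjectHits(ot)[best]
  dmrIdx <- queryHits(ot)[best]
  nearest <- closestGene(tes(features)[teIdx], genes(features))
  out <- data.frame(te_id = nearest$te_id, gene_id = nearest$gene_id,
                    methDiff = dmrs$diff[dmrIdx])
  out$log2fc <- expression$log2fc[match(out$gene_id, expression$gene_id)]
  if (significantOnly) {
    sig <- expression$significant[match(out$gene_id, expression$gene_id)]
    out <- out[!is.na(sig) & sig, , drop = FALSE]
  }
  out <- out[!is.na(out$log2fc) & is.finite(out$log2fc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methylation-expression correlation report
#'
#' Runs the full linkage procedure on called DMRs: gates genes on RRG
#' coverage (>= \code{minGeneCoverage} bases) and TEs on any coverage,
#' builds the three contingency universes (DMR in gene body, DMR in
#' promoter, DMR in TE with nearest-gene mapping) against the DEG calls,
#' and applies the exact Fisher test to each.
#'
#' @param dmrs GRanges of DMRs.
#' @param features a \linkS4class{FeatureSet}.
#' @param rrg an \linkS4class{RRGIntervalSet}.
#' @param expression expression data.frame.
#' @param minGeneCoverage gene coverage gate in bp.
#' @return list with per-universe contingency tables and p-values, the DM
#'   gene sets and the DM-and-DE percentage for the gene-body universe.
#' @export
correlateMethylationExpression <- function(dmrs, features, rrg, expression,
                                           minGeneCoverage = 500L) {
  geneCov <- featureCoverage(rrg, genes(features))
  eligibleGenes <- gateGenes(geneCov, minGeneCoverage)
  deGenes <- expression$gene_id[expression$significant]
  dmGene <- unique(genes(features)$gene_id[
    overlapsAny(genes(features), dmrs, ignore.strand = TRUE)])
  dmProm <- unique(promoters2k(features)$gene_id[
    overlapsAny(promoters2k(features), dmrs, ignore.strand = TRUE)])
  tabGene <- buildContingency(eligibleGenes,
                              intersect(dmGene, eligibleGenes),
                              intersect(deGenes, eligibleGenes))
  tabProm <- buildContingency(eligibleGenes,
                              intersect(dmProm, eligibleGenes),
                              intersect(deGenes, eligibleGenes))
  ## TE universe: deduplicated nearest genes of RRG-covered TEs; a gene is
  ## DM when it is the nearest gene of a covered TE containing a DMR
  teResult <- NULL
  if (length(tes(features))) {
    teCov <- featureCoverage(rrg, tes(features))
    covered <- which(teCov >= 1L)
    if (length(covered)) {
      nearest <- closestGene(tes(features)[covered], genes(features))
      universe <- unique(nearest$gene_id[!is.na(nearest$gene_id)])
      dmTe <- overlapsAny(tes(features)[covered], dmrs,
                          ignore.strand = TRUE)
      dmNearest <- unique(nearest$gene_id[dmTe & !is.na(nearest$gene_id)])
      tabTe <- buildContingency(universe, dmNearest,
                                intersect(deGenes, universe))
      teResult <- list(table = tabTe, p = fisherExactTest(tabTe),
                       dmGenes = dmNearest)
    }
  }
  dmDePct <- if (tabGene@a + tabGene@b > 0)
    dmDePercentage(tabGene@a, tabGene@a + tabGene@b) else NA_integer_
  list(gene = list(table = tabGene, p = fisherExactTest(tabGene),
                   dmGenes = intersect(dmGene, eligibleGenes),
                   dmDePercent = dmDePct),
       promoter = list(table = tabProm, p = fisherExactTest(tabProm),
                       dmGenes = intersect(dmProm, eligibleGenes)),
       te = teResult,
       eligibleGenes = eligibleGenes)
}
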