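## Expression-table handling: log2 fold changes, DEG summaries and overlaps,
## TE-containing-transcript summaries.

#' Log2 fold change of expression
#'
#' \code{log2(treatment / control)}.  A zero control FPKM leaves the ratio
#' undefined (\code{NA}, rendered as a dash in printed tables); a zero
#' treatment FPKM with positive control gives \code{-Inf}.
#'
#' @param fpkmControl,fpkmTreatment non-negative FPKM values (vectorised).
#' @return Numeric log2 fold changes.
#' @examples
#' log2FoldChange(170.3, 674.5)  # 1.99
#' log2FoldChange(0, 159.8)      # NA (undefined)
#' @export
log2FoldChange <- function(fpkmControl, fpkmTreatment) {
  if (any(fpkmControl < 0, na.rm = TRUE) ||
      any(fpkmTreatment < 0, na.rm = TRUE))
    stop("FPKM values must be non-negative")
  ifelse(fpkmControl == 0, NA_real_,
         ifelse(fpkmTreatment == 0, -Inf,
                log2(fpkmTreatment / fpkmControl)))
}

#' Read / write a tab-separated expression table
#'
#' Expected columns (tolerant of naming dialects): gene id, control and
#' treatment FPKM, and a yes/no significance flag; optional locus, log2fc
#' and q-value columns are passed through when present.  The log2 fold
#' change and direction are recomputed from the FPKM columns when absent.
#'
#' @param path file path.
#' @return data.frame with gene_id, fpkm_control, fpkm_treatment, log2fc,
#'   significant (logical) and direction (up/down/NA).
#' @export
readExpressionTable <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, skip = "gene_id")
  nm <- names(dt)
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) NULL else dt[[i]]
  }
  gene <- pick(c("gene_id", "gene", "id"))
  fc0 <- pick(c("fpkm_control", "fpkm_a", "fpkm_1", "value_1"))
  fc1 <- pick(c("fpkm_treatment", "fpkm_b", "fpkm_2", "value_2"))
  sig <- pick(c("significant", "sig"))
  if (is.null(gene) || is.null(fc0) || is.null(fc1))
    stop("expression table must provide gene id and two FPKM columns")
  sig <- if (is.null(sig)) rep(FALSE, length(gene))
         else tolower(as.character(sig)) %in% c("yes", "true", "1")
  lfc <- log2FoldChange(fc0, fc1)
  data.frame(gene_id = as.character(gene), fpkm_control = fc0,
             fpkm_treatment = fc1, log2fc = lfc, significant = sig,
             direction = ifelse(sig & !is.na(lfc) & lfc > 0, "up",
                         ifelse(sig & !is.na(lfc) & lfc < 0, "down",
                                NA_character_)))
}

#' @param records expression data.frame as returned by
#'   \code{readExpressionTable} or the simulator.
#' @rdname readExpressionTable
#' @export
writeExpressionTable <- function(records, path) {
  out <- data.table(gene_id = records$gene_id,
                    fpkm_control = records$fpkm_control,
                    fpkm_treatment = records$fpkm_treatment,
                    significant = ifelse(records$significant, "yes", "no"))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Summary of differentially expressed genes
#'
#' @param records expression data.frame.
#' @return list: nSignificant, nUp, nDown, upShare, downShare (shares NA
#'   when nothing is significant).
#' @export
degSummary <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  nUp <- sum(sig$direction == "up", na.rm = TRUE)
  nDown <- sum(sig$direction == "down", na.rm = TRUE)
  n <- nrow(sig)
  list(nSignificant = n, nUp = nUp, nDown = nDown,
       upShare = if (n) nUp / n else NA_real_,
       downShare = if (n) nDown / n else NA_real_)
}

#' Overlap of DEG sets between two treatments
#'
#' Partitions the union of significant genes of both treatments; every
#' significant gene is counted exactly once.
#'
#' @param recordsA,recordsB expression data.frames of the two treatments
#'   sharing a gene-id namespace.
#' @return Named integer vector: aOnlyUp, aOnlyDown, bOnlyUp, bOnlyDown,
#'   sharedSame, sharedOpposite.
#' @export
degOverlap <- function(recordsA, recordsB) {
  sa <- recordsA[recordsA$significant, c("gene_id", "direction")]
  sb <- recordsB[recordsB$significant, c("gene_id", "direction")]
  shared <- intersect(sa$gene_id, sb$gene_id)
  aOnly <- sa[!sa$gene_id %in% shared, ]
  bOnly <- sb[!sb$gene_id %in% shared, ]
  da <- sa$direction[match(shared, sa$gene_id)]
  db <- sb$direction[match(shared, sb$gene_id)]
  c(aOnlyUp = sum(aOnly$direction == "up", na.rm = TRUE),
    aOnlyDown = sum(aOnly$direction == "down", na.rm = TRUE),
    bOnlyUp = sum(bOnly$direction == "up", na.rm = TRUE),
    bOnlyDown = sum(bOnly$direction == "down", na.rm = TRUE),
    sharedSame = sum(da == db, na.rm = TRUE),
    sharedOpposite = sum(da != db, na.rm = TRUE))
}

#' TE-containing transcripts and their mean expression change
#'
#' Counts transcripts overlapping any transposable element and reports the
#' mean percent FPKM change between conditions among those with positive
#' control FPKM.
#'
#' @param records expression data.frame (gene_id keyed).
#' @param transcripts GRanges of transcript coordinates with \code{gene_id}.
#' @param tes GRanges of transposable elements.
#' @return list: nTeTranscripts, meanChangePercent (NA when no TE-containing
#'   transcript has positive control FPKM).
#' @export
teTranscriptSummary <- function(records, transcripts, tes) {
  ov <- overlapsAny(transcripts, tes, ignore.strand = TRUE)
  teGenes <- unique(transcripts$gene_id[ov])
  sel <- records[records$gene_id %in% teGenes &
                 records$fpkm_control > 0, , drop = FALSE]
  change <- if (nrow(sel))
    mean(100 * (sel$fpkm_treatment - sel$fpkm_control) / sel$fpkm_control)
  else NA_real_
  list(nTeTranscripts = length(teGenes), meanChangePercent = change)
}
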