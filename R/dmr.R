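## Kernel-smoothed two-proportion score test and DMR assembly.
##
## Pipeline per context: restrict to cytosines adequately covered in both
## conditions; smooth counts with a triangular kernel; score-test each
## cytosine on the smoothed counts; assemble maximal runs of qualifying
## cytosines (gap <= window); re-test each region on unsmoothed pooled
## counts and apply the size/count/difference/significance filters.

#' Construct DMR calling parameters
#'
#' @param preset \code{"strict"} (window 500 bp, min size 50 bp, >= 4
#'   cytosines with >= 4 reads each, |difference| >= 0.40, p <= 0.01) or
#'   \code{"relaxed"} (>= 3 cytosines with >= 3 reads, |difference| >= 0.10).
#' @param window,minSize,minCytosines,minReadsPerCytosine,minDiff,pMax
#'   individual overrides of the preset values.
#' @param adjust \code{"none"} (default; regions filtered on raw p) or
#'   \code{"BH"} (Benjamini-Hochberg adjusted region p-values).
#' @return A \linkS4class{DMRParams} object.
#' @examples
#' dmrParams("strict")
#' dmrParams("relaxed")
#' @export
dmrParams <- function(preset = c("strict", "relaxed"), window = 500,
                      minSize = 50, minCytosines = NULL,
                      minReadsPerCytosine = NULL, minDiff = NULL,
                      pMax = 0.01, adjust = c("none", "BH")) {
  preset <- match.arg(preset)
  if (is.null(minCytosines))
    minCytosines <- if (preset == "strict") 4L else 3L
  if (is.null(minReadsPerCytosine))
    minReadsPerCytosine <- if (preset == "strict") 4L else 3L
  if (is.null(minDiff))
    minDiff <- if (preset == "strict") 0.40 else 0.10
  new("DMRParams", window = window, minSize = minSize,
      minCytosines = as.integer(minCytosines),
      minReadsPerCytosine = as.integer(minReadsPerCytosine),
      minDiff = minDiff, pMax = pMax, kernel = "triangular",
      adjust = match.arg(adjust))
}

#' Triangular-kernel smoothed counts around a position
#'
#' Each same-context cytosine at distance d from the focal position
#' contributes its counts with weight w(d) = max(0, 1 - |d| / halfWidth):
#' full weight at the focal position, linearly decaying to zero at (and
#' beyond) \code{halfWidth}.
#'
#' @param positions cytosine positions (bp, one chromosome).
#' @param methylated,total counts aligned with \code{positions}.
#' @param at focal position.
#' @param halfWidth kernel half-width in bp (> 0).
#' @return Numeric c(m, n): kernel-weighted methylated and total counts
#'   (c(0, 0) when no cytosine falls inside the window).
#' @export
triangularSmooth <- function(positions, methylated, total, at, halfWidth) {
  stopifnot(halfWidth > 0)
  w <- pmax(0, 1 - abs(positions - at) / halfWidth)
  c(m = sum(w * methylated), n = sum(w * total))
}

## smoothed counts at every site of one chromosome, vectorised
.smoothChrom <- function(pos, m, n, halfWidth) {
  win <- IRanges(pos - ceiling(halfWidth) + 1L, pos + ceiling(halfWidth) - 1L)
  hits <- findOverlaps(IRanges(pos, width = 1L), win)
  focal <- subjectHits(hits)   # window owner
  nb <- queryHits(hits)        # contributing site
  w <- pmax(0, 1 - abs(pos[nb] - pos[focal]) / halfWidth)
  ms <- rowsum(w * m[nb], focal)
  ns <- rowsum(w * n[nb], focal)
  out <- matrix(0, length(pos), 2)
  idx <- as.integer(rownames(ms))
  out[idx, 1] <- ms[, 1]
  out[idx, 2] <- ns[, 1]
  out
}

#' Two-proportion score test
#'
#' z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2)) with phat the pooled
#' proportion; p is the two-sided normal tail.  Degenerate pooled
#' proportions (phat of exactly 0 or 1, i.e. no variability) return z = 0,
#' p = 1.  Vectorised.
#'
#' @param m1,n1 methylated and total counts in group 1.
#' @param m2,n2 methylated and total counts in group 2.
#' @return data.frame with columns \code{z} and \code{p}.
#' @examples
#' scoreTest(8, 10, 2, 10)  # z = 2.683, p = 0.0073
#' @export
scoreTest <- function(m1, n1, m2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("score test requires positive totals in both groups")
  phat <- (m1 + m2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (m1 / n1 - m2 / n2) / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
  data.frame(z = z, p = p)
}

#' Call differentially methylated regions between two conditions
#'
#' @param control,treatment \linkS4class{PooledCondition} objects (replicate
#'   counts already pooled).
#' @param context \code{"CG"}, \code{"CHG"} or \code{"CHH"}.
#' @param params a \linkS4class{DMRParams} object.
#' @return GRanges of DMRs with metadata columns: context, nCytosines,
#'   methControl/totalControl, methTreatment/totalTreatment, propControl,
#'   propTreatment, diff (treatment - control), pValue and direction
#'   (\code{"hypo"} when the treatment is less methylated).
#' @details The algorithm: (1) keep same-context cytosines with at least
#'   \code{minReadsPerCytosine} pooled reads in both conditions; (2) smooth
#'   each condition's counts with a triangular kernel of half-width
#'   window/2 and score-test the smoothed counts at each cytosine; (3) take
#'   maximal runs of qualifying cytosines (smoothed p <= pMax and smoothed
#'   |difference| >= minDiff) with inter-cytosine gaps <= window; (4)
#'   re-test each region on its unsmoothed pooled counts; (5) keep regions
#'   with length >= minSize, >= minCytosines cytosines, region |difference|
#'   >= minDiff and region p <= pMax.  Region significance deliberately uses
#'   unsmoothed counts so it is not doubly smoothed.
#' @export
callDMRs <- function(control, treatment, context, params = dmrParams()) {
  .checkContext(context)
  stopifnot(is(params, "DMRParams"))
  a <- sites(control)
  b <- sites(treatment)
  da <- data.table(chrom = as.character(seqnames(a)), position = start(a),
                   strand. = as.character(strand(a)),
                   mA = as.numeric(a$methylated), nA = as.numeric(a$total))[
                     a$context == context]
  db <- data.table(chrom = as.character(seqnames(b)), position = start(b),
                   strand. = as.character(strand(b)),
                   mB = as.numeric(b$methylated), nB = as.numeric(b$total))[
                     b$context == context]
  dd <- merge(da, db, by = c("chrom", "position", "strand."))
  dd <- dd[dd$nA >= params@minReadsPerCytosine &
             dd$nB >= params@minReadsPerCytosine]
  setorder(dd, chrom, position)
  emptyOut <- GRanges(context = character(), nCytosines = integer(),
                      methControl = numeric(), totalControl = numeric(),
                      methTreatment = numeric(), totalTreatment = numeric(),
                      propControl = numeric(), propTreatment = numeric(),
                      diff = numeric(), pValue = numeric(),
                      direction = character())
  if (!nrow(dd)) return(emptyOut)
  hw <- params@window / 2
  regions <- list()
  for (chromName in unique(dd$chrom)) {
    selC <- dd$chrom == chromName
    pos <- dd$position[selC]
    mA <- dd$mA[selC]; nA <- dd$nA[selC]
    mB <- dd$mB[selC]; nB <- dd$nB[selC]
    smA <- .smoothChrom(pos, mA, nA, hw)
    smB <- .smoothChrom(pos, mB, nB, hw)
    valid <- smA[, 2] > 0 & smB[, 2] > 0
    st <- scoreTest(pmax(smA[, 1], 0)[valid], smA[valid, 2],
                    pmax(smB[, 1], 0)[valid], smB[valid, 2])
    diffS <- smB[valid, 1] / smB[valid, 2] - smA[valid, 1] / smA[valid, 2]
    qual <- logical(length(pos))
    qual[valid] <- st$p <= params@pMax & abs(diffS) >= params@minDiff
    qpos <- pos[qual]
    if (!length(qpos)) next
    runId <- cumsum(c(1, diff(qpos) > params@window))
    for (r in unique(runId)) {
      rs <- range(qpos[runId == r])
      inReg <- pos >= rs[1] & pos <= rs[2]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chromName, start = rs[1], end = rs[2],
        nCytosines = sum(inReg),
        methControl = sum(mA[inReg]), totalControl = sum(nA[inReg]),
        methTreatment = sum(mB[inReg]), totalTreatment = sum(nB[inReg]))
    }
  }
  if (!length(regions)) return(emptyOut)
  reg <- do.call(rbind, regions)
  reg$propControl <- reg$methControl / reg$totalControl
  reg$propTreatment <- reg$methTreatment / reg$totalTreatment
  reg$diff <- reg$propTreatment - reg$propControl
  reg$pValue <- scoreTest(reg$methControl, reg$totalControl,
                          reg$methTreatment, reg$totalTreatment)$p
  pFilter <- if (params@adjust == "BH") p.adjust(reg$pValue, "BH")
             else reg$pValue
  keep <- (reg$end - reg$start + 1) >= params@minSize &
    reg$nCytosines >= params@minCytosines &
    abs(reg$diff) >= params@minDiff &
    pFilter <= params@pMax
  reg <- reg[keep, , drop = FALSE]
  if (!nrow(reg)) return(emptyOut)
  gr <- GRanges(reg$chrom, IRanges(reg$start, reg$end),
                context = context, nCytosines = reg$nCytosines,
                methControl = reg$methControl,
                totalControl = reg$totalControl,
                methTreatment = reg$methTreatment,
                totalTreatment = reg$totalTreatment,
                propControl = reg$propControl,
                propTreatment = reg$propTreatment,
                diff = reg$diff, pValue = reg$pValue,
                direction = ifelse(reg$diff < 0, "hypo", "hyper"))
  sl <- seqlengths(sites(control))
  if (length(sl) && !anyNA(sl)) {
    seqlevels(gr) <- names(sl)
    seqlengths(gr) <- sl
  }
  sort(gr)
}

#' Hypomethylation summary of a DMR set
#'
#' @param dmrs GRanges from \code{\link{callDMRs}}.
#' @return data.frame per context: nTotal, nHypo and fracHypo (NA when no
#'   DMRs of that context exist).
#' @export
dmrDirectionSummary <- function(dmrs) {
  if (!length(dmrs))
    return(data.frame(context = NA_character_, nTotal = 0L, nHypo = 0L,
                      fracHypo = NA_real_))
  df <- data.frame(context = dmrs$context, hypo = dmrs$direction == "hypo")
  out <- do.call(rbind, lapply(split(df, df$context), function(x)
    data.frame(context = x$context[1], nTotal = nrow(x),
               nHypo = sum(x$hypo), fracHypo = mean(x$hypo))))
  rownames(out) <- NULL
  out
}
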