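## Central S4 classes.  Genomic data live in GRanges/DNAStringSet; the classes
## here bundle them with the invariants the pipeline relies on.

#' Simulation configuration
#'
#' Parameters of the synthetic RRBS study: a small TE-rich genome, two
#' conditions (nutrient-replete control and a deficiency treatment), planted
#' hypomethylated regions and planted differentially expressed genes.
#'
#' Defaults mirror the study design the simulator emulates: context baselines
#' CG 0.27, CHG 0.19, CHH 0.013; three replicates per condition; bisulfite
#' conversion 0.99; a 0.5 methylation-proportion drop inside planted DMRs;
#' 85% of the genome covered by transposable elements.
#'
#' @slot genomeLength bases per chromosome.
#' @slot nChromosomes number of chromosomes.
#' @slot teFraction target fraction of the genome covered by TEs.
#' @slot nGenes number of (non-overlapping) genes.
#' @slot baselineLevels named numeric, true methylation proportion per
#'   context (\code{CG}, \code{CHG}, \code{CHH}).
#' @slot nPlantedDmrs number of planted differentially methylated regions.
#' @slot dmrEffect true proportion drop in the deficiency condition inside
#'   planted regions (floored at 0).
#' @slot dmrWidth width in bp of each planted region.
#' @slot dmrMinCytosines minimum number of same-context cytosines a planted
#'   region must contain.
#' @slot dmrContextWeights named numeric, relative share of planted DMRs per
#'   context.  CHH weight must be 0 unless \code{allowChhDmrs}.
#' @slot allowChhDmrs allow planting CHH DMRs (off by default; the analysis
#'   this emulates found none).
#' @slot coverageMean mean reads per cytosine (Poisson).
#' @slot conversionRate fraction of unmethylated cytosines successfully
#'   bisulfite-converted; failures read as methylated.
#' @slot nReplicates replicates per condition.
#' @slot nPlantedDegs number of planted differentially expressed genes.
#' @slot linkedFraction fraction of planted DEGs that are the nearest gene to
#'   a planted TE-resident DMR.
#' @slot ccggSpacing mean spacing (bp) of additionally seeded CCGG sites;
#'   \code{NA} seeds none beyond those arising by chance.
#' @slot seed integer random seed; all randomness derives from it via named
#'   sub-streams.
#' @export
setClass("SimulationConfig", representation(
  genomeLength = "numeric",
  nChromosomes = "integer",
  teFraction = "numeric",
  nGenes = "integer",
  baselineLevels = "numeric",
  nPlantedDmrs = "integer",
  dmrEffect = "numeric",
  dmrWidth = "numeric",
  dmrMinCytosines = "integer",
  dmrContextWeights = "numeric",
  allowChhDmrs = "logical",
  coverageMean = "numeric",
  conversionRate = "numeric",
  nReplicates = "integer",
  nPlantedDegs = "integer",
  linkedFraction = "numeric",
  ccggSpacing = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  p <- c(object@teFraction, object@baselineLevels, object@conversionRate,
         object@dmrEffect, object@linkedFraction)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    msg <- c(msg, "all proportions must lie in [0, 1]")
  if (!all(c("CG", "CHG", "CHH") %in% names(object@baselineLevels)))
    msg <- c(msg, "baselineLevels must name CG, CHG and CHH")
  if (object@genomeLength < 10000)
    msg <- c(msg, "genomeLength must be at least 10000")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be at least 1")
  if (object@coverageMean <= 0) msg <- c(msg, "coverageMean must be positive")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be at least 1")
  if (object@nPlantedDegs > object@nGenes)
    msg <- c(msg, "nPlantedDegs cannot exceed nGenes")
  w <- object@dmrContextWeights
  if (length(w) && (any(w < 0) || sum(w) <= 0))
    msg <- c(msg, "dmrContextWeights must be non-negative with positive sum")
  if (!object@allowChhDmrs && "CHH" %in% names(w) && w[["CHH"]] > 0)
    msg <- c(msg, "CHH DMRs cannot be planted unless allowChhDmrs is TRUE")
  if (length(msg)) msg else TRUE
})

#' Ground-truth methylation state of a simulated study
#'
#' @slot sites GRanges of every cytosine with metadata columns
#'   \code{context}, \code{pControl} and \code{pTreatment} (true methylation
#'   proportions per condition).
#' @slot dmrs GRanges of planted differentially methylated regions with
#'   columns \code{context} and \code{direction}.
#' @slot degs data.frame of planted differentially expressed genes:
#'   \code{gene_id}, \code{direction} (up/down), \code{linked} (nearest gene
#'   to a planted TE-resident DMR).
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("MethylationTruth", representation(
  sites = "GRanges",
  dmrs = "GRanges",
  degs = "data.frame",
  config = "SimulationConfig"
))

setValidity("MethylationTruth", function(object) {
  msg <- character()
  sl <- seqlengths(object@dmrs)
  if (length(object@dmrs)) {
    if (any(is.na(sl)))
      msg <- c(msg, "planted DMRs must carry seqlengths")
    else if (any(end(object@dmrs) > sl[as.character(seqnames(object@dmrs))]) ||
             any(start(object@dmrs) < 1L))
      msg <- c(msg, "planted DMRs must lie within chromosome bounds")
  }
  pc <- object@sites$pControl
  pt <- object@sites$pTreatment
  if (length(pc) && (any(pc < 0 | pc > 1) || any(pt < 0 | pt > 1)))
    msg <- c(msg, "true proportions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Reduced representation genome intervals
#'
#' Fragments retained after in-silico restriction digestion and size
#' selection.  The retained intervals are disjoint; \code{genomeFraction} is
#' the retained base count over the genome size.
#'
#' @slot intervals disjoint GRanges of retained fragments.
#' @slot totalBases total retained bases.
#' @slot genomeFraction retained bases / genome bases (\code{NA} when the
#'   genome size is unknown).
#' @export
setClass("RRGIntervalSet", representation(
  intervals = "GRanges",
  totalBases = "numeric",
  genomeFraction = "numeric"
))

setValidity("RRGIntervalSet", function(object) {
  msg <- character()
  if (!isDisjoint(object@intervals))
    msg <- c(msg, "retained intervals must be disjoint")
  if (sum(width(object@intervals)) != object@totalBases)
    msg <- c(msg, "totalBases must equal the summed interval widths")
  gf <- object@genomeFraction
  if (!is.na(gf) && (gf < 0 || gf > 1))
    msg <- c(msg, "genomeFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DMR calling parameters
#'
#' Thresholds of the kernel-smoothed two-proportion score test and the region
#' filters.  The strict preset is: window 500 bp, minimum region size 50 bp,
#' at least 4 cytosines with at least 4 reads each in both conditions, a
#' methylation proportion difference of at least 0.40 and p below 0.01.  The
#' relaxed preset lowers these to 3 cytosines, 3 reads and a 0.10 difference.
#'
#' @slot window smoothing window in bp (kernel half-width = window / 2); also
#'   the maximum gap between consecutive qualifying cytosines of one region.
#' @slot minSize minimum region size in bp.
#' @slot minCytosines minimum number of cytosines per region.
#' @slot minReadsPerCytosine minimum pooled reads per cytosine, per condition.
#' @slot minDiff minimum absolute methylation proportion difference.
#' @slot pMax maximum score-test p-value.
#' @slot kernel smoothing kernel; only \code{"triangular"} is implemented.
#' @slot adjust p-value adjustment applied to region p-values before the
#'   \code{pMax} filter: \code{"none"} (default) or \code{"BH"}.
#' @export
setClass("DMRParams", representation(
  window = "numeric",
  minSize = "numeric",
  minCytosines = "integer",
  minReadsPerCytosine = "integer",
  minDiff = "numeric",
  pMax = "numeric",
  kernel = "character",
  adjust = "character"
))

setValidity("DMRParams", function(object) {
  msg <- character()
  if (object@minSize <= 0 || object@minSize > object@window)
    msg <- c(msg, "minSize must satisfy 0 < minSize <= window")
  if (object@minDiff <= 0 || object@minDiff > 1)
    msg <- c(msg, "minDiff must lie in (0, 1]")
  if (object@pMax <= 0 || object@pMax >= 1)
    msg <- c(msg, "pMax must lie in (0, 1)")
  if (!identical(object@kernel, "triangular"))
    msg <- c(msg, "only the triangular kernel is implemented")
  if (!object@adjust %in% c("none", "BH"))
    msg <- c(msg, "adjust must be 'none' or 'BH'")
  if (length(msg)) msg else TRUE
})

#' Genomic feature set: genes, promoters, transposable elements
#'
#' @slot genes stranded GRanges with a \code{gene_id} column.
#' @slot tes GRanges of transposable elements with a \code{te_id} column.
#' @slot promoters stranded GRanges derived from the genes (2000 bp upstream
#'   of each 5' end, truncated at chromosome edges) carrying the parent
#'   \code{gene_id}.
#' @export
setClass("FeatureSet", representation(
  genes = "GRanges",
  tes = "GRanges",
  promoters = "GRanges"
))

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (length(object@genes)) {
    if (is.null(object@genes$gene_id))
      msg <- c(msg, "genes must carry a gene_id column")
    if (any(strand(object@genes) == "*"))
      msg <- c(msg, "genes must be stranded")
  }
  if (length(object@promoters) && is.null(object@promoters$gene_id))
    msg <- c(msg, "promoters must carry their parent gene_id")
  if (length(msg)) msg else TRUE
})

#' Pooled per-condition cytosine counts
#'
#' Replicate counts of one condition summed cytosine-by-cytosine, the unit on
#' which methylation summaries and DMR calling operate.
#'
#' @slot sites GRanges of cytosines (strand set) with metadata columns
#'   \code{context}, \code{methylated} and \code{total}.
#' @slot condition condition label (e.g. \code{"control"}, \code{"-N"}).
#' @export
setClass("PooledCondition", representation(
  sites = "GRanges",
  condition = "character"
))

setValidity("PooledCondition", function(object) {
  msg <- character()
  mc <- mcols(object@sites)
  need <- c("context", "methylated", "total")
  if (!all(need %in% colnames(mc))) {
    msg <- c(msg, "sites must carry context, methylated and total columns")
  } else {
    if (any(mc$methylated < 0) || any(mc$total < mc$methylated))
      msg <- c(msg, "counts must satisfy 0 <= methylated <= total")
    if (!all(mc$context %in% c("CG", "CHG", "CHH")))
      msg <- c(msg, "context must be CG, CHG or CHH")
  }
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single label")
  if (length(msg)) msg else TRUE
})

#' 2x2 contingency table of differential methylation and expression
#'
#' @slot a genes both differentially methylated and expressed.
#' @slot b genes only differentially methylated.
#' @slot c genes only differentially expressed.
#' @slot d genes neither.
#' @export
setClass("ContingencyTable2x2",
         representation(a = "numeric", b = "numeric",
                        c = "numeric", d = "numeric"))

setValidity("ContingencyTable2x2", function(object) {
  v <- c(object@a, object@b, object@c, object@d)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    "cells must be non-negative integers" else TRUE
})
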