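#' @name methylink-accessors
#' @title Accessors for methylink classes
#' @description Accessor generics for the package's S4 containers.
#' @param x an object.
#' @return The slot contents.
NULL

#' @rdname methylink-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname methylink-accessors
#' @export
setGeneric("tes", function(x) standardGeneric("tes"))
#' @rdname methylink-accessors
#' @export
setGeneric("promoters2k", function(x) standardGeneric("promoters2k"))
#' @rdname methylink-accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname methylink-accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname methylink-accessors
#' @export
setGeneric("rrgRanges", function(x) standardGeneric("rrgRanges"))
#' @rdname methylink-accessors
#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))
#' @rdname methylink-accessors
#' @export
setGeneric("genomeFraction", function(x) standardGeneric("genomeFraction"))
#' @rdname methylink-accessors
#' @export
setGeneric("plantedDmrs", function(x) standardGeneric("plantedDmrs"))
#' @rdname methylink-accessors
#' @export
setGeneric("plantedDegs", function(x) standardGeneric("plantedDegs"))

#' @rdname methylink-accessors
#' @export
setMethod("genes", "FeatureSet", function(x) x@genes)
#' @rdname methylink-accessors
#' @export
setMethod("tes", "FeatureSet", function(x) x@tes)
#' @rdname methylink-accessors
#' @export
setMethod("promoters2k", "FeatureSet", function(x) x@promoters)
#' @rdname methylink-accessors
#' @export
setMethod("sites", "PooledCondition", function(x) x@sites)
#' @rdname methylink-accessors
#' @export
setMethod("sites", "MethylationTruth", function(x) x@sites)
#' @rdname methylink-accessors
#' @export
setMethod("condition", "PooledCondition", function(x) x@condition)
#' @rdname methylink-accessors
#' @export
setMethod("rrgRanges", "RRGIntervalSet", function(x) x@intervals)
#' @rdname methylink-accessors
#' @export
setMethod("totalBases", "RRGIntervalSet", function(x) x@totalBases)
#' @rdname methylink-accessors
#' @export
setMethod("genomeFraction", "RRGIntervalSet", function(x) x@genomeFraction)
#' @rdname methylink-accessors
#' @export
setMethod("plantedDmrs", "MethylationTruth", function(x) x@dmrs)
#' @rdname methylink-accessors
#' @export
setMethod("plantedDegs", "MethylationTruth", function(x) x@degs)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("%d chromosome(s) x %g bp", object@nChromosomes,
              object@genomeLength), "\n")
  cat("  TE fraction:", object@teFraction, " genes:", object@nGenes, "\n")
  cat("  baselines:",
      paste(names(object@baselineLevels), object@baselineLevels,
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  planted DMRs: %d (effect %.2f)  planted DEGs: %d (linked %.2f)\n",
              object@nPlantedDmrs, object@dmrEffect, object@nPlantedDegs,
              object@linkedFraction))
  cat(sprintf("  coverage: %g x  conversion: %.3f  replicates: %d  seed: %d\n",
              object@coverageMean, object@conversionRate, object@nReplicates,
              object@seed))
})

setMethod("show", "MethylationTruth", function(object) {
  cat("MethylationTruth:", length(object@sites), "cytosines,",
      length(object@dmrs), "planted DMRs,",
      nrow(object@degs), "planted DEGs\n")
})

setMethod("show", "RRGIntervalSet", function(object) {
  cat("RRGIntervalSet:", length(object@intervals), "fragments,",
      object@totalBases, "bases",
      if (!is.na(object@genomeFraction))
        sprintf("(%.1f%% of genome)", 100 * object@genomeFraction) else "",
      "\n")
})

setMethod("show", "DMRParams", function(object) {
  cat(sprintf(paste0("DMRParams: window %g bp, minSize %g bp, ",
                     ">=%d cytosines, >=%d reads/cytosine, |diff| >= %.2f, ",
                     "p <= %g (%s kernel, adjust=%s)\n"),
              object@window, object@minSize, object@minCytosines,
              object@minReadsPerCytosine, object@minDiff, object@pMax,
              object@kernel, object@adjust))
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", length(object@genes), "genes,",
      length(object@promoters), "promoters,",
      length(object@tes), "TEs\n")
})

setMethod("show", "PooledCondition", function(object) {
  cat("PooledCondition '", object@condition, "': ",
      length(object@sites), " cytosines\n", sep = "")
})

setMethod("show", "ContingencyTable2x2", function(object) {
  m <- matrix(c(object@a, object@b, object@c, object@d), 2, 2, byrow = TRUE,
              dimnames = list(c("DM", "not DM"), c("DE", "not DE")))
  cat("2x2 contingency table (genes):\n")
  print(m)
})
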