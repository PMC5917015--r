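## End-to-end driver: simulate (or load) inputs, reduce the genome, pool
## replicates, summarise methylation, call DMRs per context, annotate them
## and run the methylation-expression linkage.

#' Assemble a pipeline configuration
#'
#' Exactly one of \code{simulation} (a \linkS4class{SimulationConfig}) or
#' \code{inputs} (paths to genome FASTA, gene GFF3, TE BED, cytosine
#' reports per condition and an expression table) must be given.
#'
#' @param simulation a \linkS4class{SimulationConfig}, or NULL.
#' @param inputs named list with elements \code{genome}, \code{genes},
#'   \code{tes}, \code{control} (vector of cytosine-report paths),
#'   \code{treatment} (ditto), \code{expression}; or NULL.
#' @param dmrPreset \code{"strict"} or \code{"relaxed"}.
#' @param contexts contexts to analyse.
#' @param sizeSelection RRG size-selection dialect, \code{"virtual-reference"}
#'   (20-400 bp) or \code{"library"} (40-220 bp).
#' @param minGeneCoverage RRG coverage gate for genes (bp).
#' @param outDir optional directory for the machine-readable report.
#' @return list of class \code{"methylinkConfig"}.
#' @export
pipelineConfig <- function(simulation = NULL, inputs = NULL,
                           dmrPreset = c("strict", "relaxed"),
                           contexts = c("CG", "CHG", "CHH"),
                           sizeSelection = c("virtual-reference", "library"),
                           minGeneCoverage = 500L, outDir = NULL) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of 'simulation' or 'inputs' must be provided")
  structure(list(simulation = simulation, inputs = inputs,
                 dmrPreset = match.arg(dmrPreset),
                 contexts = match.arg(contexts, several.ok = TRUE),
                 sizeSelection = match.arg(sizeSelection),
                 minGeneCoverage = minGeneCoverage, outDir = outDir),
            class = "methylinkConfig")
}

#' Validate pipeline inputs
#'
#' Returns issues instead of raising; \code{\link{runPipeline}} refuses to
#' start on any error-severity issue.  Checks file existence and format
#' sniffing for file inputs, configuration validity for simulation runs,
#' feature coordinate sanity and the context vocabulary.
#'
#' @param config a configuration from \code{\link{pipelineConfig}}.
#' @return data.frame with columns \code{severity} (\code{"error"} or
#'   \code{"warning"}) and \code{message}; zero rows when everything is
#'   well-formed.
#' @export
validateInputs <- function(config) {
  issues <- data.frame(severity = character(), message = character())
  add <- function(sev, msg)
    rbind(issues, data.frame(severity = sev, message = msg))
  if (!inherits(config, "methylinkConfig"))
    return(add("error", "config must come from pipelineConfig()"))
  bad <- setdiff(config$contexts, c("CG", "CHG", "CHH"))
  if (length(bad))
    issues <- add("error", paste("unknown context:", paste(bad, collapse = ",")))
  if (!is.null(config$simulation)) {
    v <- validObject(config$simulation, test = TRUE)
    if (!isTRUE(v))
      issues <- add("error", paste("simulation config:", paste(v, collapse = "; ")))
    return(issues)
  }
  inp <- config$inputs
  need <- c("genome", "genes", "control", "treatment", "expression")
  for (k in need)
    if (is.null(inp[[k]]))
      issues <- add("error", paste("missing input:", k))
  if (nrow(issues)) return(issues)
  paths <- c(inp$genome, inp$genes, inp$tes, inp$control, inp$treatment,
             inp$expression)
  for (p in paths)
    if (!file.exists(p))
      issues <- add("error", paste("file not found:", p))
  if (nrow(issues)) return(issues)
  sniff <- function(p) readLines(p, n = 1L, warn = FALSE)
  if (!startsWith(sniff(inp$genome), ">"))
    issues <- add("error", paste("not FASTA:", inp$genome))
  if (!grepl("^##gff|^#|\t", sniff(inp$genes)))
    issues <- add("error", paste("not GFF3:", inp$genes))
  if (is.null(inp$tes)) {
    issues <- add("warning", "no TE annotation: TE stages will be skipped")
  } else if (file.size(inp$tes) == 0) {
    issues <- add("warning", "empty TE file: TE stages will be skipped")
  }
  if (!nrow(issues[issues$severity == "error", , drop = FALSE])) {
    genome <- readDNAStringSet(inp$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    g <- tryCatch(rtracklayer::import(inp$genes), error = function(e) NULL)
    if (is.null(g)) {
      issues <- add("error", paste("unreadable GFF3:", inp$genes))
    } else {
      onKnown <- as.character(seqnames(g)) %in% names(genome)
      if (!all(onKnown))
        issues <- add("error", "gene(s) on chromosomes absent from genome")
      lim <- width(genome)[match(as.character(seqnames(g)), names(genome))]
      if (any(onKnown & (end(g) > lim | start(g) < 1L), na.rm = TRUE))
        issues <- add("error", "gene(s) beyond chromosome end")
    }
  }
  issues
}

.loadInputs <- function(inp) {
  genome <- readDNAStringSet(inp$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  g <- rtracklayer::import(inp$genes)
  gid <- if (!is.null(g$ID)) g$ID else paste0("gene", seq_along(g))
  genes <- GRanges(seqnames(g), ranges(g), strand = strand(g),
                   gene_id = as.character(gid))
  seqlevels(genes) <- names(genome)
  seqlengths(genes) <- width(genome)
  tes <- GRanges()
  if (!is.null(inp$tes) && file.exists(inp$tes) && file.size(inp$tes) > 0) {
    t <- rtracklayer::import(inp$tes)
    tes <- GRanges(seqnames(t), ranges(t))
    seqlevels(tes) <- names(genome)
    seqlengths(tes) <- width(genome)
  }
  list(genome = genome, features = featureSet(genes, tes),
       reports = list(
         control = lapply(inp$control, readCytosineReport),
         treatment = lapply(inp$treatment, readCytosineReport)),
       expression = readExpressionTable(inp$expression))
}

#' Run the full RRBS analysis pipeline
#'
#' Stages: simulate (or load) inputs -> in-silico digestion and size
#' selection -> replicate pooling -> methylation summaries per context and
#' condition -> DMR calling per context -> feature classification ->
#' methylation-expression contingency analysis.  Every report number equals
#' the value of the corresponding module function on the same inputs.
#'
#' @param config a configuration from \code{\link{pipelineConfig}}.
#' @return list report: globalLevels, dmrCounts, directionSummary,
#'   featureShares, correlation (contingency tables and Fisher p-values),
#'   scatter, plus the intermediate objects (rrg, dmrs, pooled, data).
#' @export
runPipeline <- function(config) {
  issues <- validateInputs(config)
  err <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(err))
    stop("invalid inputs:\n", paste("-", err$message, collapse = "\n"))
  data <- if (!is.null(config$simulation))
    simulateMethylome(config$simulation)
  else .loadInputs(config$inputs)

  rrg <- sizeSelect(digestGenome(data$genome), preset = config$sizeSelection)
  pooled <- list(
    control = poolReplicates(data$reports$control, "control"),
    treatment = poolReplicates(data$reports$treatment, "treatment"))

  globalLevels <- lapply(pooled, function(p)
    vapply(config$contexts, function(ctx)
      tryCatch(globalContextLevel(p, ctx), error = function(e) NA_real_),
      numeric(1)))

  params <- dmrParams(config$dmrPreset)
  dmrs <- lapply(setNames(config$contexts, config$contexts), function(ctx)
    callDMRs(pooled$control, pooled$treatment, ctx, params))
  allDmrs <- suppressWarnings(do.call(c, unname(dmrs)))

  shares <- if (length(allDmrs))
    featureShare(classifyDMRs(allDmrs, data$features)) else NULL
  corr <- if (length(genes(data$features)))
    correlateMethylationExpression(allDmrs, data$features, rrg,
                                   data$expression,
                                   config$minGeneCoverage) else NULL
  scatter <- scatterData(allDmrs, data$features, data$expression)

  report <- list(
    genomeFraction = genomeFraction(rrg),
    globalLevels = globalLevels,
    dmrCounts = vapply(dmrs, length, integer(1)),
    directionSummary = dmrDirectionSummary(allDmrs),
    featureShares = shares,
    degSummary = degSummary(data$expression),
    correlation = if (!is.null(corr)) list(
      geneTable = c(a = corr$gene$table@a, b = corr$gene$table@b,
                    c = corr$gene$table@c, d = corr$gene$table@d),
      geneP = corr$gene$p,
      geneDmDePercent = corr$gene$dmDePercent,
      promoterP = corr$promoter$p,
      teP = if (!is.null(corr$te)) corr$te$p else NA_real_) else NULL,
    nScatterPairs = nrow(scatter))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      ## named vectors serialize as JSON objects, not nameless arrays
      jsonReady <- function(x) {
        if (is.data.frame(x)) x
        else if (is.list(x)) lapply(x, jsonReady)
        else if (is.atomic(x) && !is.null(names(x))) as.list(x)
        else x
      }
      jsonlite::write_json(jsonReady(report),
                           file.path(config$outDir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    } else {
      warning("jsonlite not available: machine-readable report not written")
    }
  }
  c(report, list(rrg = rrg, dmrs = dmrs, pooled = pooled,
                 scatter = scatter, data = data))
}
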