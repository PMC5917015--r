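## Synthetic RRBS study generator: a small TE-rich genome, ground-truth
## methylation with planted hypomethylated regions, binomial bisulfite
## count reports per replicate, and an expression table with planted DEGs,
## optionally linked to TE-resident planted DMRs.

#' Construct a simulation configuration
#'
#' Defaults describe the emulated study: a TE-rich (85%) genome, context
#' baselines CG 0.27 / CHG 0.19 / CHH 0.013, a 0.5 methylation drop inside
#' planted regions, 3 replicates per condition, Poisson coverage and 99%
#' bisulfite conversion.  See \linkS4class{SimulationConfig} for every
#' field.
#'
#' @param genomeLength bases per chromosome (>= 10000).
#' @param nChromosomes number of chromosomes.
#' @param teFraction target TE-covered fraction of the genome.
#' @param nGenes number of non-overlapping genes.
#' @param baselineLevels named true methylation proportions per context.
#' @param nPlantedDmrs planted DMR count.
#' @param dmrEffect true proportion drop inside planted regions.
#' @param dmrWidth planted region width (bp).  The default (1200) is more
#'   than twice the DMR caller's 500 bp smoothing window: only cytosines
#'   whose whole kernel window lies inside the region are guaranteed the
#'   full planted difference, so the recoverable core spans about
#'   width - window bases.  Regions narrower than the window are attenuated
#'   below a strict difference threshold and are not recoverable.
#' @param dmrMinCytosines minimum same-context cytosines per planted region.
#' @param dmrContextWeights relative planting share per context (CHH must be
#'   0 unless \code{allowChhDmrs}).
#' @param allowChhDmrs permit CHH planting (for power studies only).
#' @param coverageMean mean reads per cytosine.
#' @param conversionRate bisulfite conversion rate.
#' @param nReplicates replicates per condition.
#' @param nPlantedDegs planted DEG count.
#' @param linkedFraction fraction of planted DEGs that must be the nearest
#'   gene to a planted TE-resident DMR.
#' @param ccggSpacing mean spacing of additionally seeded CCGG sites
#'   (\code{NA}: none).
#' @param seed integer seed; all randomness flows from it.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(genomeLength = 1e6, nChromosomes = 1L,
                             teFraction = 0.85, nGenes = 50L,
                             baselineLevels = c(CG = 0.27, CHG = 0.19,
                                                CHH = 0.013),
                             nPlantedDmrs = 20L, dmrEffect = 0.5,
                             dmrWidth = 1200L, dmrMinCytosines = 6L,
                             dmrContextWeights = c(CG = 0.9, CHG = 0.1),
                             allowChhDmrs = FALSE,
                             coverageMean = 10, conversionRate = 0.99,
                             nReplicates = 3L, nPlantedDegs = 10L,
                             linkedFraction = 0.5, ccggSpacing = 200,
                             seed = 1L) {
  new("SimulationConfig", genomeLength = genomeLength,
      nChromosomes = as.integer(nChromosomes), teFraction = teFraction,
      nGenes = as.integer(nGenes), baselineLevels = baselineLevels,
      nPlantedDmrs = as.integer(nPlantedDmrs), dmrEffect = dmrEffect,
      dmrWidth = dmrWidth, dmrMinCytosines = as.integer(dmrMinCytosines),
      dmrContextWeights = dmrContextWeights, allowChhDmrs = allowChhDmrs,
      coverageMean = coverageMean, conversionRate = conversionRate,
      nReplicates = as.integer(nReplicates),
      nPlantedDegs = as.integer(nPlantedDegs),
      linkedFraction = linkedFraction, ccggSpacing = ccggSpacing,
      seed = as.integer(seed))
}

#' Generate a toy TE-rich genome with gene and TE annotations
#'
#' Chromosome sequences are drawn uniformly over A/C/G/T with additional
#' CCGG sites seeded at a controllable mean spacing, so the in-silico
#' digestion yields a dense fragment population.  TEs are uniform random
#' intervals with log-normal lengths, allowed to overlap genes (TEs nest in
#' genic regions in TE-rich genomes), placed until their union covers the
#' target fraction.  Genes are non-overlapping stranded intervals.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list: \code{genome} (DNAStringSet) and \code{features}
#'   (\linkS4class{FeatureSet}).
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(subSeed(config@seed, "genome"), {
    L <- as.integer(config@genomeLength)
    chromNames <- paste0("chr", seq_len(config@nChromosomes))
    seqs <- vapply(chromNames, function(chromName) {
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (!is.na(config@ccggSpacing) && config@ccggSpacing > 0) {
        nSites <- max(1L, floor(L / config@ccggSpacing))
        starts <- sort(sample.int(L - 3L, min(nSites, L - 3L)))
        ## drop seeded sites closer than 4 bp so motifs don't clobber
        keep <- c(TRUE, diff(starts) >= 4L)
        for (s in starts[keep]) chars[s:(s + 3L)] <- c("C", "C", "G", "G")
      }
      paste(chars, collapse = "")
    }, character(1))
    genome <- DNAStringSet(seqs)
    names(genome) <- chromNames
    totalBases <- as.numeric(L) * config@nChromosomes
    si <- Seqinfo(chromNames, rep(L, config@nChromosomes))

    ## TEs: overlapping log-normal intervals placed in batches until their
    ## union covers the target fraction (then trimmed back to the first
    ## batch position that reached it)
    tes <- GRanges(seqinfo = si)
    if (config@teFraction > 0) {
      target <- config@teFraction * totalBases
      unionBases <- function(gr) sum(as.numeric(width(reduce(gr))))
      acc <- GRanges(seqinfo = si)
      rounds <- 0L
      while (unionBases(acc) < target && rounds < 500L) {
        rounds <- rounds + 1L
        batch <- 200L
        chromName <- sample(chromNames, batch, replace = TRUE)
        len <- pmax(200L, pmin(L, as.integer(round(rlnorm(batch, log(2000), 0.7)))))
        s <- vapply(len, function(l) sample.int(L - l + 1L, 1L), integer(1))
        cand <- GRanges(chromName, IRanges(s, s + len - 1L), seqinfo = si)
        if (unionBases(c(acc, cand)) >= target) {
          ## binary-search the shortest batch prefix reaching the target so
          ## the final coverage barely overshoots it
          lo <- 1L; hi <- batch
          while (lo < hi) {
            mid <- (lo + hi) %/% 2L
            if (unionBases(c(acc, cand[seq_len(mid)])) >= target) hi <- mid
            else lo <- mid + 1L
          }
          acc <- c(acc, cand[seq_len(lo)])
          break
        }
        acc <- c(acc, cand)
      }
      if (unionBases(acc) < target)
        warning("TE placement stopped before reaching the target fraction")
      tes <- sort(acc)
    }
    if (length(tes)) tes$te_id <- paste0("te", seq_along(tes))

    ## genes: non-overlapping stranded intervals (plain-vector rejection
    ## sampling; S4 construction deferred to the end)
    gChrom <- character(0); gStart <- integer(0); gEnd <- integer(0)
    attempts <- 0L
    maxAttempts <- 300L * config@nGenes
    while (length(gStart) < config@nGenes && attempts < maxAttempts) {
      attempts <- attempts + 1L
      len <- as.integer(round(runif(1, 1500, 4000)))
      if (len >= L) next
      chromName <- sample(chromNames, 1L)
      s <- sample.int(L - len + 1L, 1L)
      e <- s + len - 1L
      same <- gChrom == chromName
      if (any(same & gStart <= e & gEnd >= s)) next
      gChrom <- c(gChrom, chromName)
      gStart <- c(gStart, s)
      gEnd <- c(gEnd, e)
    }
    if (length(gStart) < config@nGenes)
      stop("could not place ", config@nGenes,
           " non-overlapping genes: genome capacity exceeded")
    genes <- GRanges(gChrom, IRanges(gStart, gEnd),
                     strand = sample(c("+", "-"), length(gStart),
                                     replace = TRUE),
                     seqinfo = si)
    genes <- sort(genes, ignore.strand = TRUE)
    genes$gene_id <- sprintf("gene%03d", seq_along(genes))
    list(genome = genome, features = featureSet(genes, tes))
  })
}

#' Plant ground-truth methylation and hypomethylated regions
#'
#' Every cytosine receives its context baseline proportion in both
#' conditions; inside planted regions the deficiency-condition proportion
#' drops by \code{dmrEffect} (floored at 0).  Planted regions are windows of
#' \code{dmrWidth} bp containing at least \code{dmrMinCytosines} cytosines
#' of their context; CHH regions are never planted unless
#' \code{allowChhDmrs} (the emulated analysis found no CHH DMRs).
#'
#' @param genome DNAStringSet from \code{\link{simulateGenome}}.
#' @param features the matching \linkS4class{FeatureSet}.
#' @param config the \linkS4class{SimulationConfig}.
#' @return A \linkS4class{MethylationTruth}.
#' @export
plantMethylation <- function(genome, features, config) {
  stopifnot(is(config, "SimulationConfig"))
  cyt <- findCytosines(genome)
  base <- config@baselineLevels[cyt$context]
  cyt$pControl <- unname(base)
  cyt$pTreatment <- unname(base)
  si <- seqinfo(cyt)

  dmrs <- GRanges(seqinfo = si)
  if (config@nPlantedDmrs > 0L) {
    w <- config@dmrContextWeights
    w <- w[w > 0]
    ## deterministic largest-remainder allocation of DMRs across contexts
    raw <- config@nPlantedDmrs * w / sum(w)
    nPer <- floor(raw)
    rem <- config@nPlantedDmrs - sum(nPer)
    if (rem > 0) {
      extra <- order(raw - nPer, decreasing = TRUE)[seq_len(rem)]
      nPer[extra] <- nPer[extra] + 1L
    }
    dmrs <- withSeed(subSeed(config@seed, "dmrs"), {
      dChrom <- character(0); dStart <- integer(0); dEnd <- integer(0)
      dCtx <- character(0)
      ## sorted context-cytosine positions per chromosome for fast
      ## findInterval window counts
      posIdx <- lapply(setNames(nm = names(nPer)), function(ctx) {
        sel <- cyt[cyt$context == ctx]
        split(start(sel), as.character(seqnames(sel)))
      })
      w <- as.integer(config@dmrWidth)
      for (ctx in names(nPer)) {
        needed <- as.integer(nPer[[ctx]])
        if (needed == 0L) next
        placedCtx <- 0L
        attempts <- 0L
        maxAttempts <- 2000L * needed
        while (placedCtx < needed && attempts < maxAttempts) {
          attempts <- attempts + 1L
          chromName <- sample(seqlevels(si), 1L)
          maxStart <- seqlengths(si)[chromName] - w + 1L
          if (maxStart < 1L) break
          s <- sample.int(maxStart, 1L)
          e <- s + w - 1L
          pos <- posIdx[[ctx]][[chromName]]
          if (is.null(pos)) next
          nCtx <- findInterval(e, pos) - findInterval(s - 1L, pos)
          if (nCtx < config@dmrMinCytosines) next
          ## keep planted regions > 1 kb apart: the caller merges
          ## qualifying runs separated by <= window, so closer truth
          ## regions would fuse into a single called region
          sep <- 1000L
          if (any(dChrom == chromName & dStart <= e + sep &
                    dEnd >= s - sep)) next
          dChrom <- c(dChrom, chromName)
          dStart <- c(dStart, s)
          dEnd <- c(dEnd, e)
          dCtx <- c(dCtx, ctx)
          placedCtx <- placedCtx + 1L
        }
        if (placedCtx < needed)
          stop("could not place ", needed, " planted DMRs in the ", ctx,
               " context (cytosine density too low)")
      }
      out <- GRanges(dChrom, IRanges(dStart, dEnd), context = dCtx,
                     direction = "hypo", seqinfo = si)
      sort(out)
    })
    ## lower the deficiency-condition truth inside matching-context regions
    ov <- findOverlaps(cyt, dmrs, ignore.strand = TRUE)
    inReg <- ov[cyt$context[queryHits(ov)] == dmrs$context[subjectHits(ov)]]
    idx <- unique(queryHits(inReg))
    cyt$pTreatment[idx] <- pmax(0, cyt$pControl[idx] - config@dmrEffect)
    ## planted regions must contain enough cytosines of their context
    counts <- tabulate(subjectHits(inReg), nbins = length(dmrs))
    stopifnot(all(counts >= pmin(config@dmrMinCytosines, 4L)))
  }

  degs <- data.frame(gene_id = character(), direction = character(),
                     linked = logical())
  new("MethylationTruth", sites = cyt, dmrs = dmrs, degs = degs,
      config = config)
}

#' Simulate per-replicate bisulfite cytosine reports
#'
#' Per cytosine and replicate, total reads are Poisson around
#' \code{coverageMean} and methylated reads binomial with observed success
#' probability p_obs = p_true + (1 - p_true)(1 - conversionRate): a
#' conversion failure leaves an unmethylated cytosine reading as
#' methylated.  Zero-coverage rows are kept (downstream filters drop them).
#'
#' @param truth a \linkS4class{MethylationTruth}.
#' @param config the \linkS4class{SimulationConfig}.
#' @param regions optional GRanges restricting reported cytosines (e.g. the
#'   RRG intervals).
#' @return list of two lists of GRanges (\code{control} and
#'   \code{treatment}), one GRanges per replicate with metadata columns
#'   context, methylated, total, sample_id.
#' @export
simulateCounts <- function(truth, config, regions = NULL) {
  stopifnot(is(truth, "MethylationTruth"))
  cyt <- sites(truth)
  if (!is.null(regions))
    cyt <- cyt[overlapsAny(cyt, regions, ignore.strand = TRUE)]
  n <- length(cyt)
  pObs <- function(p) p + (1 - p) * (1 - config@conversionRate)
  withSeed(subSeed(config@seed, "counts"), {
    sim <- lapply(c(control = "pControl", treatment = "pTreatment"),
                  function(col) {
      p <- pObs(mcols(cyt)[[col]])
      cond <- if (col == "pControl") "control" else "treatment"
      lapply(seq_len(config@nReplicates), function(r) {
        total <- rpois(n, config@coverageMean)
        meth <- rbinom(n, total, p)
        gr <- granges(cyt)
        gr$context <- cyt$context
        gr$methylated <- meth
        gr$total <- total
        gr$sample_id <- sprintf("%s_rep%d", cond, r)
        gr
      })
    })
    names(sim) <- c("control", "treatment")
    sim
  })
}

#' Simulate an expression table with planted DEGs
#'
#' Control FPKMs are log-normal; planted DEGs receive a fold change of at
#' least 2 in their planted direction and a TRUE significance flag;
#' non-planted genes get small log-normal wobble and FALSE flags.  A
#' \code{linkedFraction} share of planted DEGs is chosen from the nearest
#' genes of planted TE-resident DMRs so that the TE-level contingency test
#' has a detectable alternative.
#'
#' @param features the \linkS4class{FeatureSet}.
#' @param truth the \linkS4class{MethylationTruth} (planted DMRs define the
#'   linkable genes).
#' @return list: \code{expression} (data.frame) and \code{truth} (the input
#'   truth with its planted-DEG table filled in).
#' @inheritParams simulateCounts
#' @export
simulateExpression <- function(features, truth, config) {
  stopifnot(config@nPlantedDegs <= length(genes(features)))
  geneIds <- genes(features)$gene_id
  withSeed(subSeed(config@seed, "expression"), {
    fpkm0 <- rlnorm(length(geneIds), log(20), 1.2)
    nLinked <- as.integer(round(config@linkedFraction * config@nPlantedDegs))
    nUnlinked <- config@nPlantedDegs - nLinked
    linkedIds <- character()
    if (nLinked > 0L) {
      teDmrs <- plantedDmrs(truth)[
        overlapsAny(plantedDmrs(truth), tes(features),
                    ignore.strand = TRUE)]
      if (!length(teDmrs))
        stop("linkage requested but no planted TE-resident DMRs exist")
      ## nearest gene of the TE hosting each planted DMR
      ot <- findOverlaps(teDmrs, tes(features), ignore.strand = TRUE)
      hostTes <- tes(features)[unique(subjectHits(ot))]
      nearest <- closestGene(hostTes, genes(features))
      pool <- unique(nearest$gene_id[!is.na(nearest$gene_id)])
      if (length(pool) < nLinked) {
        warning("only ", length(pool), " unique nearest genes of planted ",
                "TE-resident DMRs available; linked DEG count capped")
        nLinked <- length(pool)
      }
      linkedIds <- sample(pool, nLinked)
    }
    freeIds <- setdiff(geneIds, linkedIds)
    otherIds <- if (nUnlinked > 0) sample(freeIds, nUnlinked)
                else character()
    plantedIds <- c(linkedIds, otherIds)
    direction <- sample(c("up", "down"), length(plantedIds), replace = TRUE)
    lfc <- numeric(length(geneIds))
    lfc[match(plantedIds, geneIds)] <-
      ifelse(direction == "up", 1, -1) * runif(length(plantedIds), 1, 4)
    wobble <- rnorm(length(geneIds), 0, 0.15)
    wobble[match(plantedIds, geneIds)] <- 0
    fpkm1 <- fpkm0 * 2^(lfc + wobble)
    significant <- geneIds %in% plantedIds
    expr <- data.frame(
      gene_id = geneIds, fpkm_control = fpkm0, fpkm_treatment = fpkm1,
      log2fc = log2FoldChange(fpkm0, fpkm1), significant = significant,
      direction = ifelse(significant,
                         direction[match(geneIds, plantedIds)],
                         NA_character_))
    truth@degs <- data.frame(gene_id = plantedIds, direction = direction,
                             linked = plantedIds %in% linkedIds)
    list(expression = expr, truth = truth)
  })
}

#' Run the full synthetic-study generator
#'
#' Genome, annotations, ground truth, per-replicate cytosine reports and
#' the expression table, all from one seed.  With \code{dir} set, writes
#' FASTA (genome), BED (TEs), GFF3 (genes), one cytosine report per
#' replicate and the expression table.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir optional output directory.
#' @return list: genome, features, truth, reports (control/treatment lists
#'   of GRanges), expression.
#' @export
simulateMethylome <- function(config = simulationConfig(), dir = NULL) {
  gen <- simulateGenome(config)
  truth <- plantMethylation(gen$genome, gen$features, config)
  reports <- simulateCounts(truth, config)
  expr <- simulateExpression(gen$features, truth, config)
  out <- list(genome = gen$genome, features = gen$features,
              truth = expr$truth, reports = reports,
              expression = expr$expression)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(out$genome, file.path(dir, "genome.fa"))
    if (length(tes(out$features)))
      rtracklayer::export(tes(out$features), file.path(dir, "tes.bed"))
    g <- genes(out$features)
    g$type <- "gene"
    g$ID <- g$gene_id
    rtracklayer::export(g, file.path(dir, "genes.gff3"))
    for (cond in names(out$reports))
      for (r in seq_along(out$reports[[cond]]))
        writeCytosineReport(out$reports[[cond]][[r]],
                            file.path(dir, sprintf("%s_rep%d.tsv", cond, r)))
    writeExpressionTable(out$expression, file.path(dir, "expression.tsv"))
  }
  out
}
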