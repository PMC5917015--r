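suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

## fixtures computed once per test run
.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## moderate simulated study with strong planted CG DMRs, shared across tests
simFixture <- function() fixture("sim", function() {
  cfg <- simulationConfig(
    genomeLength = 2e5, nGenes = 20, nPlantedDmrs = 8, nPlantedDegs = 6,
    baselineLevels = c(CG = 0.8, CHG = 0.19, CHH = 0.013),
    dmrContextWeights = c(CG = 1), coverageMean = 20,
    linkedFraction = 0.5, seed = 101)
  sim <- simulateMethylome(cfg)
  sim$pooledControl <- poolReplicates(sim$reports$control, "control")
  sim$pooledTreatment <- poolReplicates(sim$reports$treatment, "treatment")
  sim$config <- cfg
  sim
})

## fully linked study: every planted DEG is the nearest gene of a planted
## TE-resident DMR (no count simulation; truth-level fixture)
linkedSimFixture <- function() fixture("linkedSim", function() {
  cfg <- simulationConfig(
    genomeLength = 1.5e5, nGenes = 40, nPlantedDmrs = 25, nPlantedDegs = 20,
    baselineLevels = c(CG = 0.8, CHG = 0.19, CHH = 0.013),
    dmrContextWeights = c(CG = 1), linkedFraction = 1, seed = 21)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  ex <- suppressWarnings(simulateExpression(gen$features, truth, cfg))
  list(gen = gen, truth = ex$truth, expression = ex$expression)
})

## a pooled condition built from explicit site tables
makePooled <- function(pos, context, methylated, total, condition = "cond",
                       chrom = "chr1", strandChar = "+", seqLen = 10000L) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = strandChar,
                context = context, methylated = methylated, total = total)
  seqlengths(gr) <- setNames(seqLen, chrom)
  new("PooledCondition", sites = gr, condition = condition)
}

## reciprocal-overlap recovery of truth regions by called regions
recoveredFraction <- function(truth, called, minReciprocal = 0.5) {
  if (!length(truth)) return(NA_real_)
  hits <- findOverlaps(truth, called)
  rec <- vapply(seq_along(truth), function(i) {
    j <- subjectHits(hits)[queryHits(hits) == i]
    if (!length(j)) return(FALSE)
    ov <- width(pintersect(rep(ranges(truth)[i], length(j)),
                           ranges(called)[j]))
    any(ov >= minReciprocal * width(truth)[i] &
          ov >= minReciprocal * width(called)[j])
  }, logical(1))
  mean(rec)
}

## independent two-sided Fisher p by explicit enumeration over all tables
## with the observed margins, using choose() directly
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  pr <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  pObs <- pr[match(a, xs)]
  sum(pr[pr <= pObs * (1 + 1e-7)])
}
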