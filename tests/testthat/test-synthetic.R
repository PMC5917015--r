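test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(teFraction = 1.2), "proportions")
  expect_error(simulationConfig(genomeLength = 500), "genomeLength")
  expect_error(simulationConfig(nGenes = 200, nPlantedDegs = 300),
               "nPlantedDegs")
  expect_error(simulationConfig(dmrContextWeights = c(CG = 0.5, CHH = 0.5)),
               "CHH")
  ## CHH planting is allowed only by explicit override
  cfg <- simulationConfig(dmrContextWeights = c(CG = 0.5, CHH = 0.5),
                          allowChhDmrs = TRUE)
  expect_s4_class(cfg, "SimulationConfig")
})

test_that("TE placement hits the target coverage fraction", {
  cfg0 <- simulationConfig(genomeLength = 5e4, nGenes = 3, teFraction = 0,
                           nPlantedDmrs = 0, nPlantedDegs = 0,
                           linkedFraction = 0, seed = 2)
  gen0 <- simulateGenome(cfg0)
  expect_equal(length(tes(gen0$features)), 0L)
  sim <- simFixture()
  frac <- sum(width(reduce(tes(sim$features)))) /
    sim$config@genomeLength
  expect_gte(frac, 0.80)
  expect_lte(frac, 0.90)
  ## genes are non-overlapping and stranded
  g <- genes(sim$features)
  expect_true(isDisjoint(g))
  expect_true(all(strand(g) %in% c("+", "-")))
})

test_that("identical seed and config reproduce byte-identical outputs", {
  cfg <- simulationConfig(genomeLength = 2e4, nGenes = 3, nPlantedDmrs = 2,
                          nPlantedDegs = 2, linkedFraction = 0,
                          baselineLevels = c(CG = 0.8, CHG = 0.19,
                                             CHH = 0.013),
                          dmrContextWeights = c(CG = 1), seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  simulateMethylome(cfg, dir = d1)
  simulateMethylome(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("planted regions lower the deficiency truth by the effect size", {
  cfg <- simulationConfig(genomeLength = 5e4, nGenes = 5, nPlantedDmrs = 3,
                          nPlantedDegs = 0, linkedFraction = 0,
                          baselineLevels = c(CG = 0.8, CHG = 0.19,
                                             CHH = 0.013),
                          dmrEffect = 0.5, dmrContextWeights = c(CG = 1),
                          seed = 4)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  s <- sites(truth)
  inDmr <- overlapsAny(s, plantedDmrs(truth), ignore.strand = TRUE) &
    s$context == "CG"
  expect_equal(unique(s$pTreatment[inDmr]), 0.3)
  expect_true(all(s$pTreatment[!inDmr] == s$pControl[!inDmr]))
  ## every planted region contains enough cytosines of its context
  ov <- findOverlaps(s, plantedDmrs(truth), ignore.strand = TRUE)
  match_ctx <- s$context[queryHits(ov)] ==
    plantedDmrs(truth)$context[subjectHits(ov)]
  counts <- tabulate(subjectHits(ov)[match_ctx],
                     nbins = length(plantedDmrs(truth)))
  expect_true(all(counts >= 4))
})

test_that("the deficiency truth is floored at zero", {
  cfg <- simulationConfig(genomeLength = 5e4, nGenes = 5, nPlantedDmrs = 2,
                          nPlantedDegs = 0, linkedFraction = 0,
                          baselineLevels = c(CG = 0.8, CHG = 0.19,
                                             CHH = 0.013),
                          dmrEffect = 0.9, dmrContextWeights = c(CG = 1),
                          seed = 4)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  s <- sites(truth)
  inDmr <- overlapsAny(s, plantedDmrs(truth), ignore.strand = TRUE) &
    s$context == "CG"
  expect_true(all(s$pTreatment[inDmr] == 0))
})

test_that("zero planted DMRs leave both conditions identical", {
  cfg <- simulationConfig(genomeLength = 2e4, nGenes = 2, nPlantedDmrs = 0,
                          nPlantedDegs = 0, linkedFraction = 0, seed = 6)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  expect_identical(sites(truth)$pControl, sites(truth)$pTreatment)
  expect_equal(length(plantedDmrs(truth)), 0L)
})

test_that("perfect conversion and zero truth give zero methylated reads", {
  cfg <- simulationConfig(genomeLength = 2e4, nGenes = 2, nPlantedDmrs = 0,
                          nPlantedDegs = 0, linkedFraction = 0,
                          baselineLevels = c(CG = 0, CHG = 0, CHH = 0),
                          conversionRate = 1, seed = 8)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  counts <- simulateCounts(truth, cfg)
  for (rep in counts$control) expect_true(all(rep$methylated == 0))
})

test_that("conversion failures converge to 1 - rate (law of large numbers)", {
  cfg <- simulationConfig(genomeLength = 1e5, nGenes = 2, nPlantedDmrs = 0,
                          nPlantedDegs = 0, linkedFraction = 0,
                          baselineLevels = c(CG = 0, CHG = 0, CHH = 0),
                          conversionRate = 0.98, coverageMean = 10, seed = 3)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  counts <- simulateCounts(truth, cfg)
  rep1 <- counts$control[[1]]
  expect_gt(length(rep1), 1e4)
  expect_equal(sum(rep1$methylated) / sum(rep1$total), 0.02,
               tolerance = 0.003 / 0.02)
})

test_that("observed context levels match baselines outside planted regions", {
  sim <- simFixture()
  s <- sites(sim$pooledControl)
  nonDmr <- !overlapsAny(s, plantedDmrs(sim$truth), ignore.strand = TRUE)
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- s[nonDmr & s$context == ctx]
    pTrue <- sim$config@baselineLevels[[ctx]]
    pObs <- pTrue + (1 - pTrue) * 0.01
    expect_gt(length(sel), 1e4)
    expect_equal(sum(sel$methylated) / sum(sel$total), pObs,
                 tolerance = 0.01 / pObs)
  }
})

test_that("counts are restricted to supplied regions when requested", {
  cfg <- simulationConfig(genomeLength = 2e4, nGenes = 2, nPlantedDmrs = 0,
                          nPlantedDegs = 0, linkedFraction = 0, seed = 12)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  rrg <- GRanges("chr1", IRanges(1, 5000))
  counts <- simulateCounts(truth, cfg, regions = rrg)
  expect_true(all(end(counts$control[[1]]) <= 5000))
})

test_that("planted DEGs carry the promised fold changes and flags", {
  cfg <- simulationConfig(genomeLength = 5e4, nGenes = 10, nPlantedDmrs = 0,
                          nPlantedDegs = 0, linkedFraction = 0, seed = 5)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  ex0 <- simulateExpression(gen$features, truth, cfg)
  expect_true(all(!ex0$expression$significant))
  cfg2 <- simulationConfig(genomeLength = 5e4, nGenes = 10,
                           nPlantedDmrs = 0, nPlantedDegs = 4,
                           linkedFraction = 0, seed = 5)
  ex <- simulateExpression(gen$features, truth, cfg2)
  sig <- ex$expression[ex$expression$significant, ]
  expect_equal(nrow(sig), 4L)
  expect_true(all(abs(sig$log2fc) >= 1))
  up <- sig[sig$direction == "up", ]
  expect_true(all(up$log2fc > 0))
  down <- sig[sig$direction == "down", ]
  expect_true(all(down$log2fc < 0))
})

test_that("full linkage places every planted DEG next to a TE DMR", {
  sim <- linkedSimFixture()
  degs <- plantedDegs(sim$truth)
  expect_true(all(degs$linked))
  ## cross-check against closestGene on the TEs hosting planted DMRs
  teDmrs <- plantedDmrs(sim$truth)[
    overlapsAny(plantedDmrs(sim$truth), tes(sim$gen$features))]
  host <- tes(sim$gen$features)[
    unique(subjectHits(findOverlaps(teDmrs, tes(sim$gen$features))))]
  nearest <- closestGene(host, genes(sim$gen$features))
  expect_true(all(degs$gene_id %in% nearest$gene_id))
})

test_that("linkage without TE-resident planted DMRs is an error", {
  cfg <- simulationConfig(genomeLength = 5e4, nGenes = 5, teFraction = 0,
                          nPlantedDmrs = 2, nPlantedDegs = 2,
                          baselineLevels = c(CG = 0.8, CHG = 0.19,
                                             CHH = 0.013),
                          dmrContextWeights = c(CG = 1),
                          linkedFraction = 1, seed = 5)
  gen <- simulateGenome(cfg)
  truth <- plantMethylation(gen$genome, gen$features, cfg)
  expect_error(simulateExpression(gen$features, truth, cfg), "TE-resident")
})
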