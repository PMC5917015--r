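test_that("context assignment follows the CG/CHG/CHH definition", {
  g <- DNAStringSet(c(chr1 = "ACGT"))
  expect_equal(assignContext(g, "chr1", 2, "+"), "CG")
  g2 <- DNAStringSet(c(chr1 = "ACAGT"))
  expect_equal(assignContext(g2, "chr1", 2, "+"), "CHG")
  g3 <- DNAStringSet(c(chr1 = "ACAAT"))
  expect_equal(assignContext(g3, "chr1", 2, "+"), "CHH")
  ## not a C on the requested strand
  expect_true(is.na(assignContext(g, "chr1", 1, "+")))
  expect_true(is.na(assignContext(g, "chr1", 2, "-")))
  ## window runs off the chromosome end
  expect_true(is.na(assignContext(DNAStringSet(c(chr1 = "AC")), "chr1", 2,
                                  "+")))
  expect_error(assignContext(g, "chr1", 9, "+"), "range")
})

test_that("the CCGG site carries symmetric CG methylation positions", {
  g <- DNAStringSet(c(chr1 = "CCGG"))
  ## forward CG cytosine at position 2; its symmetric partner is the minus
  ## cytosine paired with the G at position 3
  expect_equal(assignContext(g, "chr1", 2, "+"), "CG")
  expect_equal(assignContext(g, "chr1", 3, "-"), "CG")
  ## the minus cytosine at position 4 reads 5'-CCG-3': CHG
  expect_equal(assignContext(g, "chr1", 4, "-"), "CHG")
})

test_that("context assignment agrees with a reverse-complement oracle", {
  set.seed(11)
  seqStr <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  g <- DNAStringSet(c(chr1 = seqStr))
  cyt <- findCytosines(g)
  oracle <- function(windowStr) {
    ch <- strsplit(windowStr, "")[[1]]
    if (ch[1] != "C") return(NA_character_)
    if (length(ch) >= 2 && ch[2] == "G") return("CG")
    if (length(ch) < 3) return(NA_character_)
    if (ch[3] == "G") "CHG" else "CHH"
  }
  idx <- sample(length(cyt), 300)
  for (i in idx) {
    p <- start(cyt)[i]
    if (as.character(strand(cyt))[i] == "+") {
      win <- as.character(subseq(g[[1]], p, min(p + 2, 10000)))
    } else {
      win <- as.character(reverseComplement(
        subseq(g[[1]], max(p - 2, 1), p)))
    }
    expect_equal(cyt$context[i], oracle(win),
                 info = sprintf("pos %d strand %s", p,
                                as.character(strand(cyt))[i]))
  }
  ## every C on both strands with a full window is reported exactly once
  chars <- strsplit(seqStr, "")[[1]]
  nPlus <- sum(chars == "C") - (chars[10000] == "C")
  nMinus <- sum(chars == "G") - (chars[1] == "G")
  ## minus positions 2 and plus positions 9999 may lack the 3-base window
  ## only when not CG; tolerate the off-by-few from edge handling
  expect_gte(length(cyt), nPlus + nMinus - 4)
  expect_lte(length(cyt), nPlus + nMinus)
})

test_that("replicate pooling sums counts cytosine-by-cytosine", {
  mk <- function(m, n, sample) {
    gr <- GRanges("chr1", IRanges(100, width = 1), strand = "+",
                  context = "CG", methylated = m, total = n,
                  sample_id = sample)
    gr
  }
  pooled <- poolReplicates(list(mk(3, 10, "r1"), mk(5, 10, "r2"),
                                mk(2, 10, "r3")), "control")
  expect_equal(sites(pooled)$methylated, 10)
  expect_equal(sites(pooled)$total, 30)
  expect_equal(condition(pooled), "control")
  ## single replicate: identity
  one <- poolReplicates(mk(4, 9, "r1"))
  expect_equal(sites(one)$methylated, 4)
  expect_equal(sites(one)$total, 9)
  ## cytosine present in only some replicates contributes zero elsewhere
  r1 <- c(mk(1, 5, "r1"), GRanges("chr1", IRanges(200, width = 1),
                                  strand = "+", context = "CG",
                                  methylated = 0, total = 5,
                                  sample_id = "r1"))
  r2 <- mk(0, 5, "r2")
  p2 <- poolReplicates(list(r1, r2))
  s <- sites(p2)
  expect_equal(s$methylated[start(s) == 100], 1)
  expect_equal(s$total[start(s) == 100], 10)
  expect_equal(s$total[start(s) == 200], 5)
  ## conflicting context annotations are corrupt input
  bad <- mk(1, 5, "r2")
  bad$context <- "CHG"
  expect_error(poolReplicates(list(mk(1, 5, "r1"), bad)), "conflict")
})

test_that("pooling conserves totals and the count-weighted level is
           invariant under splitting counts across pseudo-replicates", {
  sim <- simFixture()
  reps <- sim$reports$control
  pooled <- sim$pooledControl
  expect_equal(sum(as.numeric(sites(pooled)$total)),
               sum(vapply(reps, function(r) sum(as.numeric(r$total)),
                          numeric(1))))
  ## split one pooled table into two pseudo-replicates
  s <- sites(pooled)[sites(pooled)$context == "CG"]
  s <- s[s$total >= 2][1:500]
  half <- function(x) as.integer(floor(x / 2))
  a <- s; a$methylated <- half(s$methylated); a$total <- half(s$total)
  b <- s; b$methylated <- s$methylated - a$methylated
  b$total <- s$total - a$total
  resplit <- poolReplicates(list(a, b))
  expect_equal(globalContextLevel(resplit, "CG"),
               sum(s$methylated) / sum(s$total))
})

test_that("global context level is the count-weighted proportion", {
  p <- makePooled(c(100, 200), c("CG", "CG"), c(5, 10), c(10, 10))
  expect_equal(globalContextLevel(p, "CG"), 15 / 20)
  expect_equal(globalContextLevel(p, "CG", weighted = FALSE), 0.75)
  z <- makePooled(c(100, 200), c("CG", "CG"), c(0, 0), c(8, 12))
  expect_equal(globalContextLevel(z, "CG"), 0)
  expect_error(globalContextLevel(p, "CHH"), "qualifying")
  expect_error(globalContextLevel(p, "XX"), "context")
  ## minReads filters low-coverage cytosines
  q <- makePooled(c(100, 200), c("CG", "CG"), c(5, 0), c(10, 1))
  expect_equal(globalContextLevel(q, "CG", minReads = 5), 0.5)
})

test_that("simulated control data reproduce the observed baseline level", {
  sim <- simFixture()
  ## CHG baseline 0.19, conversion 0.99: p_obs = 0.19 + 0.81 * 0.01
  lvl <- globalContextLevel(sim$pooledControl, "CHG")
  expect_equal(lvl, 0.19 + 0.81 * 0.01, tolerance = 0.01 / 0.198)
  ## CHH baseline 0.013
  lvlH <- globalContextLevel(sim$pooledControl, "CHH")
  expect_equal(lvlH, 0.013 + 0.987 * 0.01, tolerance = 0.01 / 0.0229)
})

test_that("chromosome profiles are count-weighted per bin with NA gaps", {
  p <- makePooled(c(1e6, 6e6), c("CG", "CG"), c(4, 8), c(10, 10),
                  seqLen = 2e7)
  prof <- chromosomeProfile(p, "CG", bin = 5e6)
  expect_equal(prof$level[1], 0.4)
  expect_equal(prof$level[2], 0.8)
  ## bins without cytosines are missing, not zero
  expect_true(all(is.na(prof$level[3:4])))
  expect_equal(nrow(prof), 4)
})

test_that("uniform methylation yields a flat chromosome profile", {
  sim <- simFixture()
  prof <- chromosomeProfile(sim$pooledControl, "CHG", bin = 2e4)
  lv <- prof$level[!is.na(prof$level)]
  expect_gt(length(lv), 5)
  expect_lt(max(lv) - min(lv), 0.05)
})

test_that("context shares are proportions of methylated cytosines", {
  p <- makePooled(1:100 * 10,
                  rep(c("CG", "CHG", "CHH"), c(60, 30, 10)),
                  methylated = rep(10, 100), total = rep(10, 100))
  sh <- contextShare(p)
  expect_equal(unname(sh), c(0.6, 0.3, 0.1))
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  ## single context present
  p1 <- makePooled(c(10, 20), c("CHG", "CHG"), c(9, 0), c(10, 10))
  expect_equal(unname(contextShare(p1)), c(0, 1, 0))
  ## nothing methylated at the threshold
  p0 <- makePooled(10, "CG", 0, 10)
  expect_error(contextShare(p0), "methylated")
})

test_that("conversion rate is one minus the control methylation fraction", {
  p <- makePooled(c(10, 20), c("CG", "CHH"), c(1, 1), c(50, 50))
  expect_equal(conversionRate(p), 0.98)
  p0 <- makePooled(10, "CG", 0, 100)
  expect_equal(conversionRate(p0), 1)
  pz <- makePooled(10, "CG", 0, 0)
  expect_error(conversionRate(pz), "reads")
})

test_that("simulated conversion failures recover the configured rate", {
  cfg <- simulationConfig(genomeLength = 5e4, nGenes = 2, nPlantedDmrs = 0,
                          nPlantedDegs = 0, linkedFraction = 0,
                          baselineLevels = c(CG = 0, CHG = 0, CHH = 0),
                          conversionRate = 0.99, coverageMean = 5,
                          teFraction = 0.3, seed = 5)
  sim <- simulateMethylome(cfg)
  pooled <- poolReplicates(sim$reports$control)
  expect_gt(sum(sites(pooled)$total), 1e4)
  expect_equal(conversionRate(pooled), 0.99, tolerance = 0.005 / 0.99)
})

test_that("cytosine reports round-trip through the tab-separated format", {
  sim <- simFixture()
  gr <- sim$reports$control[[1]][1:200]
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writeCytosineReport(gr, path)
  expect_true(startsWith(readLines(path, n = 1), "#"))
  back <- readCytosineReport(path)
  expect_equal(start(back), start(gr))
  expect_equal(back$methylated, gr$methylated)
  expect_equal(back$total, gr$total)
  expect_equal(back$context, gr$context)
  expect_equal(as.character(strand(back)), as.character(strand(gr)))
})
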