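test_that("context extraction reads the mutated-C strand", {
  g <- Genome(c(chr1 = "AATCAGG"))
  cat <- VariantCatalog("d", "chr1", 3L, "C", "T", genome = g)
  octx <- extractContexts(cat, g, contextWindow(1, 1))
  expect_identical(as.character(contexts(octx)), "TCA")

  # same local context on the opposite strand: G>A at the complementary base
  g2 <- Genome(c(chr1 = "CCTGAT"))
  cat2 <- VariantCatalog("d", "chr1", 3L, "G", "A", genome = g2)
  octx2 <- extractContexts(cat2, g2, contextWindow(1, 1))
  expect_identical(as.character(contexts(octx2)), "TCA")
})

test_that("contexts at chromosome edges or over N are excluded, never padded", {
  g <- Genome(c(chr1 = "CATNCA"))
  edge <- VariantCatalog("d", "chr1", 0L, "C", "T", genome = g)
  octx <- extractContexts(edge, g, contextWindow(1, 1))
  expect_identical(length(contexts(octx)), 0L)
  expect_identical(excludedCounts(octx)[["out_of_bounds"]], 1L)

  nearN <- VariantCatalog("d", "chr1", 4L, "C", "T", genome = g)
  octxN <- extractContexts(nearN, g, contextWindow(1, 1))
  expect_identical(length(contexts(octxN)), 0L)
  expect_identical(excludedCounts(octxN)[["contains_n"]], 1L)
})

test_that("information content follows 2 - H with optional small-sample correction", {
  # identical contexts: zero entropy, 2 bits everywhere
  cm <- buildContextMatrix(rep("TCA", 5), upstream = 1)
  expect_equal(unname(infoBits(cm)), c(2, 2, 2))
  expect_equal(unname(baseFreq(cm)["T", 1]), 1)

  # 25% each base at the flanks: zero bits there
  cm4 <- buildContextMatrix(c("ACA", "CCC", "GCG", "TCT"), upstream = 1)
  expect_equal(unname(infoBits(cm4)), c(0, 2, 0))

  # 2 T / 2 A at position +1: H = 1 bit so information = 1 bit
  cm2 <- buildContextMatrix(c("TCT", "TCT", "TCA", "TCA"), upstream = 1)
  expect_equal(unname(infoBits(cm2)), c(2, 2, 1))

  # small-sample correction subtracts 3/(2 n ln 2), floored at 0
  cmc <- buildContextMatrix(c("ACA", "CCC", "GCG", "TCT"), upstream = 1,
                            correction = "small_sample")
  e <- 3 / (2 * log(2) * 4)
  expect_equal(unname(infoBits(cmc)), c(0, 2 - e, 0))

  expect_error(buildContextMatrix(c("TCA", "TC"), upstream = 1),
               "same length")
})

test_that("positions and frequencies are well-formed", {
  set.seed(3)
  g <- generateGenome(simulationConfig(genomeLength = 30000, seed = 3))
  cat <- randomSnvCatalog(g, 100)
  octx <- extractContexts(cat, g, contextWindow(5, 25),
                          classes = c("C:G>T:A", "C:G>G:C", "C:G>A:T"))
  cm <- buildContextMatrix(octx)
  expect_identical(cm@positions, -5:25)
  expect_true(all(abs(colSums(baseFreq(cm)) - 1) < 1e-9))
  expect_true(all(infoBits(cm) >= 0 & infoBits(cm) <= 2))
  expect_equal(unname(infoBits(cm)[as.character(0)]), 2)  # all-C column
})

test_that("TCW fraction counts T at -1 and A/T at +1", {
  mk <- function(seqs) new("OrientedContextSet",
                           contexts = Biostrings::DNAStringSet(seqs),
                           upstream = 1L, downstream = 1L,
                           excluded = c(out_of_bounds = 0L, contains_n = 0L))
  expect_equal(tcwFraction(mk(c("TCA", "TCT"))), 1.0)
  expect_equal(tcwFraction(mk("ACG")), 0.0)
  expect_equal(tcwFraction(mk(c("TCA", "TCG", "GCA", "TCT"))), 0.5)
})

test_that("genome-wide TCW background matches a brute-force scan on a small genome", {
  set.seed(21)
  g <- generateGenome(simulationConfig(genomeLength = 1000,
                                       nChromosomes = 2L, seed = 21))
  s <- as.character(genomeSeqs(g))
  # oracle: visit every C and G with full flanks and test the oriented
  # trinucleotide by hand
  num <- 0L; den <- 0L
  for (ch in names(s)) {
    x <- strsplit(s[[ch]], "")[[1]]
    for (i in 2:(length(x) - 1)) {
      if (x[i] == "C") {
        den <- den + 1L
        if (x[i - 1] == "T" && x[i + 1] %in% c("A", "T")) num <- num + 1L
      } else if (x[i] == "G") {
        den <- den + 1L
        if (x[i + 1] == "A" && x[i - 1] %in% c("T", "A")) num <- num + 1L
      }
    }
  }
  expect_equal(cbescan:::.tcwBackground(g), num / den, tolerance = 1e-12)
})

test_that("planted APOBEC fraction is recovered through the TCW statistic", {
  cfg <- simulationConfig(genomeLength = 1e6, nApobecMutations = 700L,
                          nBackgroundMutations = 300L, nIndels = 0L,
                          seed = 97)
  sim <- simulateStudy(cfg)
  cat <- sim$catalogs[[1]]
  truth <- sim$truth
  enr <- tcwEnrichment(cat, sim$genome)
  # expected TCW fraction: all planted APOBEC events read TCW; the eligible
  # background events (C:G>T:A / C:G>G:C classes only) hit TCW at the
  # genomic rate; check the observed count against the exact binomial 99%
  # central interval given the truth records
  nApo <- sum(truth$origin == "apobec")
  nBgEligible <- enr$nObserved - nApo
  p0 <- (nApo + nBgEligible * enr$backgroundFraction) / enr$nObserved
  lo <- qbinom(0.005, enr$nObserved, p0)
  hi <- qbinom(0.995, enr$nObserved, p0)
  expect_gte(enr$nTcw, lo)
  expect_lte(enr$nTcw, hi)
  expect_gt(enr$enrichmentRatio, 3)
  expect_lt(enr$pValue, 1e-10)
})

test_that("context statistics are invariant under genome reverse-complementation", {
  cfg <- simulationConfig(genomeLength = 50000, nApobecMutations = 150L,
                          nBackgroundMutations = 50L, nIndels = 0L, seed = 13)
  sim <- simulateStudy(cfg)
  cat <- sim$catalogs[[1]]
  rc <- revcompFixture(sim$genome, cat)
  win <- contextWindow(2, 2)
  octx <- extractContexts(cat, sim$genome, win)
  octxRc <- extractContexts(rc$catalog, rc$genome, win)
  expect_equal(sort(as.character(contexts(octxRc))),
               sort(as.character(contexts(octx))))
  expect_equal(tcwFraction(octxRc), tcwFraction(octx))
  cm <- buildContextMatrix(octx); cmRc <- buildContextMatrix(octxRc)
  expect_equal(baseFreq(cmRc), baseFreq(cm))
  expect_equal(infoBits(cmRc), infoBits(cm))
  expect_equal(tcwEnrichment(rc$catalog, rc$genome)$observedFraction,
               tcwEnrichment(cat, sim$genome)$observedFraction)
})
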