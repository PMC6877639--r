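test_that("NGG detection requires a fully contained N-G-G trinucleotide", {
  expect_true(containsNgg("TAGGAC"))
  expect_false(containsNgg("ACACAC"))
  # GG at the very start has no room for the preceding N
  expect_false(containsNgg("GGAAAA"))
  expect_true(containsNgg("AGGAAA"))
  expect_error(containsNgg("ACGT"), "6 bases")
  expect_error(containsNgg("ACGTNA"), "A/C/G/T")
})

test_that("NGG hexamer fraction matches exhaustive enumeration", {
  hex <- allHexamers()
  impl <- containsNgg(hex)
  oracle <- vapply(hex, bruteContainsNgg, logical(1), USE.NAMES = FALSE)
  expect_identical(impl, oracle)
  expect_equal(mean(impl), sum(oracle) / 4096)
})

test_that("PAM windows are read 15-20 bases downstream on the mutated-C strand", {
  # C at pos 4 (0-based); +15..+20 = positions 19..24 spelling TAGGAC
  plusSeq <- paste0("AAAACAAAAAAAAAAAAAA", "TAGGAC", "AA")
  g <- Genome(c(chr1 = plusSeq))
  cat <- VariantCatalog("d", "chr1", 4L, "C", "T", genome = g)
  r <- pamProximityFraction(cat, g)
  expect_equal(r$fraction, 1.0)
  expect_identical(r$nEvaluated, 1L)

  # same site on the minus strand: G in reference, window upstream revcomp
  minusSeq <- rcChar(plusSeq)
  gM <- Genome(c(chr1 = minusSeq))
  posM <- nchar(plusSeq) - 1L - 4L
  catM <- VariantCatalog("d", "chr1", posM, "G", "A", genome = gM)
  rM <- pamProximityFraction(catM, gM)
  expect_equal(rM$fraction, 1.0)

  # an A/T-only downstream window can never hold NGG
  gAT <- Genome(c(chr1 = paste0("AAAACAAA", strrep("AT", 12))))
  catAT <- VariantCatalog("d", "chr1", 4L, "C", "T", genome = gAT)
  expect_equal(pamProximityFraction(catAT, gAT)$fraction, 0.0)
})

test_that("PAM proximity agrees with a per-variant brute-force scan", {
  set.seed(31)
  g <- generateGenome(simulationConfig(genomeLength = 1000,
                                       nChromosomes = 1L, seed = 31))
  cat <- randomSnvCatalog(g, 120)
  v <- variants(cat)
  v <- v[v$ref %in% c("C", "G"), ]
  s <- as.character(genomeSeqs(g))[[1]]
  len <- nchar(s)
  oracleHits <- 0L; oracleN <- 0L
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    if (v$ref[i] == "C") {
      from <- p + 16L; to <- p + 21L        # 1-based
      if (to > len) next
      w <- substr(s, from, to)
    } else {
      from <- p + 1L - 20L; to <- p + 1L - 15L
      if (from < 1L) next
      w <- rcChar(substr(s, from, to))
    }
    oracleN <- oracleN + 1L
    if (bruteContainsNgg(w)) oracleHits <- oracleHits + 1L
  }
  r <- pamProximityFraction(cat, g)
  expect_identical(r$nEvaluated, oracleN)
  expect_equal(r$fraction, oracleHits / oracleN)
})

test_that("PAM proximity is invariant under genome reverse-complementation", {
  set.seed(32)
  g <- generateGenome(simulationConfig(genomeLength = 5000,
                                       nChromosomes = 2L, seed = 32))
  cat <- randomSnvCatalog(g, 80)
  v <- variants(cat)
  cat <- VariantCatalog("cg", chrom = v$chrom[v$ref %in% c("C", "G")],
                        pos = v$pos[v$ref %in% c("C", "G")],
                        ref = v$ref[v$ref %in% c("C", "G")],
                        alt = v$alt[v$ref %in% c("C", "G")], genome = g)
  rc <- revcompFixture(g, cat)
  a <- pamProximityFraction(cat, g)
  b <- pamProximityFraction(rc$catalog, rc$genome)
  expect_equal(a$fraction, b$fraction)
  expect_identical(a$nEvaluated, b$nEvaluated)
})

test_that("background sampling is seeded, reproducible and sensible", {
  gA <- Genome(c(chr1 = strrep("A", 2000)))
  expect_equal(backgroundPamFrequency(gA, 500, seed = 1)$fraction, 0.0)

  set.seed(33)
  g <- generateGenome(simulationConfig(genomeLength = 100000, gcContent = 0.5,
                                       seed = 33))
  a <- backgroundPamFrequency(g, 20000, seed = 9)
  b <- backgroundPamFrequency(g, 20000, seed = 9)
  expect_identical(a, b)
  c2 <- backgroundPamFrequency(g, 20000, seed = 10)
  expect_false(identical(a$fraction, c2$fraction))
})

test_that("sampled background matches the composition-weighted enumeration value", {
  # uniform-composition genome: every hexamer equally likely, so the
  # expected NGG-containing fraction is the exhaustive hexamer fraction
  set.seed(34)
  g <- generateGenome(simulationConfig(genomeLength = 1e6, gcContent = 0.5,
                                       seed = 34))
  enum <- mean(vapply(allHexamers(), bruteContainsNgg, logical(1)))
  bg <- backgroundPamFrequency(g, 50000, seed = 11)
  expect_lt(abs(bg$fraction - enum), 3 * bg$se + 3 * sqrt(enum * (1 - enum) / 50000))
})

test_that("N-containing windows are never sampled", {
  g <- Genome(c(chr1 = paste0(strrep("A", 50), "N", strrep("TAGG", 20))))
  bg <- backgroundPamFrequency(g, 2000, seed = 2)
  expect_true(bg$fraction > 0)  # sampling proceeds around the N
  gNN <- Genome(c(chr1 = "NNNNNNNNNNNN"))
  expect_error(backgroundPamFrequency(gNN, 10, seed = 1), "no valid")
})

test_that("off-target intersection counts positional hits per site", {
  cat <- VariantCatalog("d", "chr1", 100L, "C", "T")
  sites <- data.frame(chrom = "chr1", start = 90L, end = 113L, gRNA = "HEK3",
                      mismatches = 2L, cfd = 0.5)
  r <- intersectOffTargets(cat, sites)
  expect_identical(r$total, 1L)
  expect_identical(r$perSite$nVariants, 1L)

  # half-open: position end is outside, position start is inside
  edge <- VariantCatalog("d", "chr1", c(90L, 113L), c("C", "C"), c("T", "T"))
  r2 <- intersectOffTargets(edge, sites)
  expect_identical(r2$total, 1L)

  # flank widens the window symmetrically
  r3 <- intersectOffTargets(edge, sites, flank = 1L)
  expect_identical(r3$total, 2L)

  expect_identical(intersectOffTargets(cat, sites[0, ])$total, 0L)
})

test_that("intersection totals match a quadratic brute force on random inputs", {
  set.seed(35)
  g <- generateGenome(simulationConfig(genomeLength = 5000,
                                       nChromosomes = 2L, seed = 35))
  cat <- randomSnvCatalog(g, 60)
  sites <- data.frame(chrom = sample(chromNames(g), 25, replace = TRUE),
                      start = sample.int(2400, 25),
                      gRNA = "RNF2", mismatches = 3L,
                      cfd = runif(25))
  sites$end <- sites$start + 23L
  sites <- sites[c("chrom", "start", "end", "gRNA", "mismatches", "cfd")]
  v <- variants(cat)
  brute <- 0L
  for (i in seq_len(nrow(sites)))
    for (j in seq_len(nrow(v)))
      if (sites$chrom[i] == v$chrom[j] &&
          v$pos[j] >= sites$start[i] && v$pos[j] < sites$end[i])
        brute <- brute + 1L
  expect_identical(intersectOffTargets(cat, sites)$total, brute)
})
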