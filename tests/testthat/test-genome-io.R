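test_that("FASTA reading round-trips, uppercases and records soft-masks", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "acgt"), fa)
  g <- readGenomeFasta(fa)
  expect_identical(chromNames(g), "chr1")
  expect_identical(as.character(genomeSeqs(g)[["chr1"]]), "ACGT")
  expect_identical(unname(chromLengths(g)), 4L)
  expect_identical(IRanges::start(softMask(g)$chr1), 1L)
  expect_identical(IRanges::width(softMask(g)$chr1), 4L)

  out <- withr::local_tempfile(fileext = ".fa")
  writeGenomeFasta(g, out)
  expect_identical(as.character(genomeSeqs(readGenomeFasta(out))),
                   as.character(genomeSeqs(g)))
})

test_that("FASTA degenerate inputs are hard errors", {
  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(readGenomeFasta(empty), "no records|malformed")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "TTTT"), dup)
  expect_error(readGenomeFasta(dup), "duplicate chromosome")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr2", "ACXT"), bad)
  expect_error(readGenomeFasta(bad), "line 4")
})

test_that("VCF positions convert 1-based to internal 0-based", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=100>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("chr1", "5", ".", "C", "T", ".", ".", ".", sep = "\t")),
             vcf)
  cat <- readVariantVcf(vcf)
  v <- variants(cat)
  expect_identical(v$pos, 4L)
  expect_identical(v$ref, "C")
  expect_identical(v$alt, "T")
  expect_identical(v$kind, "SNV")
})

test_that("multi-allelic VCF records split into biallelic variants", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=100>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("chr1", "5", ".", "C", "T,G", ".", ".", ".", sep = "\t")),
             vcf)
  v <- variants(readVariantVcf(vcf))
  expect_identical(nrow(v), 2L)
  expect_setequal(v$alt, c("T", "G"))
  expect_true(all(v$pos == 4L & v$ref == "C"))
})

test_that("VCF write/read round-trips a catalog including indels", {
  g <- Genome(c(chr1 = "ACGTACGTACGTACGTACGT", chr2 = "TTTTCCCCGGGGAAAA"))
  cat <- VariantCatalog("rt", chrom = c("chr1", "chr1", "chr2"),
                        pos = c(2L, 5L, 4L), ref = c("G", "CGTA", "C"),
                        alt = c("A", "C", "CTT"), genome = g)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantVcf(cat, vcf, genome = g)
  back <- readVariantVcf(vcf, genome = g, cloneId = "rt")
  expect_identical(variants(back), variants(cat))
})

test_that("VCF reading verifies ref alleles and skips symbolic ones", {
  g <- Genome(c(chr1 = "AAAAAAAAAA"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=10>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("chr1", "3", ".", "C", "T", ".", ".", ".", sep = "\t")),
             vcf)
  expect_error(readVariantVcf(vcf, genome = g), "mismatch")

  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=10>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("chr1", "3", ".", "A", "<DEL>", ".", ".", ".", sep = "\t"),
               paste("chr1", "5", ".", "A", "T", ".", ".", ".", sep = "\t")),
             vcf2)
  expect_warning(cat2 <- readVariantVcf(vcf2), "skipped")
  expect_identical(nrow(variants(cat2)), 1L)
})

test_that("unknown chromosomes never alias silently", {
  g <- Genome(c(chr1 = "ACGTACGT"))
  expect_error(
    writeVariantVcf(VariantCatalog("x", "1", 2L, "G", "A"), tempfile(),
                    genome = g),
    "not in genome")
  expect_error(
    VariantCatalog("x", "Chr1", 2L, "G", "A", genome = g),
    "not present")
})

test_that("counts tables read with 0-based conversion and validation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line",
               paste("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "n_ref",
                     "n_alt", sep = "\t"),
               paste("chr1", "7", "C", "T", "10", "12", "30", "0", sep = "\t"),
               paste("chr1", "9", "G", "A", "20", "8", "25", "1", sep = "\t"),
               paste("chr2", "3", "A", "AT", "15", "9", "28", "0", sep = "\t")),
             tsv)
  x <- readCountsTable(tsv)
  expect_identical(nrow(x), 3L)
  expect_identical(x$pos, c(6L, 8L, 2L))

  rt <- withr::local_tempfile(fileext = ".tsv")
  writeCountsTable(x, rt)
  expect_identical(readCountsTable(rt), x)
})

test_that("counts table errors name the problem", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "n_ref",
                     sep = "\t"),
               paste("chr1", "7", "C", "T", "10", "12", "30", sep = "\t")),
             bad)
  expect_error(readCountsTable(bad), "n_alt")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "n_ref",
                     "n_alt", sep = "\t"),
               paste("chr1", "7", "C", "T", "10", "-1", "30", "0", sep = "\t")),
             neg)
  expect_error(readCountsTable(neg), "negative count.*t_alt")
})

test_that("plus/minus indel dialect converts to anchored representation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "n_ref",
                     "n_alt", sep = "\t"),
               paste("chr1", "5", "A", "+TG", "10", "9", "30", "0", sep = "\t"),
               paste("chr1", "8", "C", "-AG", "10", "9", "30", "0", sep = "\t")),
             tsv)
  x <- readCountsTable(tsv, indelStyle = "plusminus")
  expect_identical(x$ref, c("A", "CAG"))
  expect_identical(x$alt, c("ATG", "C"))
})

test_that("off-target site lists round-trip in descending CFD order", {
  sites <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                      start = c(10L, 5L, 100L), end = c(33L, 28L, 123L),
                      gRNA = c("HEK3", "RNF2", "EMX1"),
                      mismatches = c(0L, 2L, 4L), cfd = c(0.9, 0.55, 0.1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeOffTargetSites(sites, tsv)
  back <- readOffTargetSites(tsv)
  expect_identical(back$cfd, sites$cfd)
  expect_identical(back$chrom, sites$chrom)

  bad <- sites; bad$end[1] <- bad$start[1]
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeOffTargetSites(bad, tsv2)
  expect_error(readOffTargetSites(tsv2), "start < end")
})
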