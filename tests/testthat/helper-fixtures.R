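## shared fixtures and independent oracles for the test suite

## brute-force one-sided Fisher p: enumerate every 2x2 table with the same
## margins and sum hypergeometric probabilities of tables at least as
## extreme (tumor alt count >= observed), computed from binomial
## coefficients only
bruteFisherP <- function(tAlt, tRef, nAlt, nRef) {
  td <- tAlt + tRef; K <- tAlt + nAlt; N <- td + nAlt + nRef
  ks <- max(0L, K - (nAlt + nRef)):min(K, td)
  pr <- choose(td, ks) * choose(N - td, K - ks) / choose(N, K)
  sum(pr[ks >= tAlt])
}

## independent NGG check: explicit offset loop rather than a regex
bruteContainsNgg <- function(w) {
  for (i in 1:4) {
    if (substr(w, i + 1L, i + 1L) == "G" && substr(w, i + 2L, i + 2L) == "G")
      return(TRUE)
  }
  FALSE
}

## all 4096 hexamers
allHexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g, 1L, paste, collapse = "")
}

## reverse complement for plain strings, independent of Biostrings
rcChar <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

## reverse-complemented genome plus the re-represented catalog: a variant at
## 0-based pos p with alleles (r, a) maps to pos len-1-p with complemented
## alleles (SNVs only)
revcompFixture <- function(genome, catalog) {
  seqs <- vapply(as.character(genomeSeqs(genome)), rcChar, character(1))
  names(seqs) <- chromNames(genome)
  g2 <- Genome(seqs)
  v <- variants(catalog)
  stopifnot(all(v$kind == "SNV"))
  lens <- chromLengths(genome)
  cat2 <- VariantCatalog(cloneId(catalog), chrom = v$chrom,
                         pos = lens[v$chrom] - 1L - v$pos,
                         ref = chartr("ACGT", "TGCA", v$ref),
                         alt = chartr("ACGT", "TGCA", v$alt), genome = g2)
  list(genome = g2, catalog = cat2)
}

## build a catalog with a prescribed class composition out of dummy
## variants; positions are spread on one long synthetic chromosome so that
## each class count is exact by construction
catalogFromClassCounts <- function(cloneId, counts) {
  stopifnot(length(counts) == 7L)
  names(counts) <- mutationClasses()
  tmpl <- list("C:G>T:A" = c("C", "T"), "C:G>G:C" = c("C", "G"),
               "C:G>A:T" = c("C", "A"), "A:T>C:G" = c("A", "C"),
               "A:T>G:C" = c("A", "G"), "A:T>T:A" = c("A", "T"))
  chrom <- character(0); ref <- character(0); alt <- character(0)
  for (cls in names(tmpl)) {
    k <- counts[[cls]]
    if (k == 0) next
    ref <- c(ref, rep(tmpl[[cls]][1], k))
    alt <- c(alt, rep(tmpl[[cls]][2], k))
  }
  nInd <- counts[["indel"]]
  if (nInd > 0) {
    ref <- c(ref, rep("A", nInd))
    alt <- c(alt, rep("AT", nInd))
  }
  n <- length(ref)
  VariantCatalog(cloneId, chrom = rep("chrS", n), pos = seq_len(n) * 10L,
                 ref = ref, alt = alt)
}

## small random catalog of SNVs on a given genome (used by property tests)
randomSnvCatalog <- function(genome, n, cloneId = "rand") {
  lens <- chromLengths(genome)
  chrom <- sample(names(lens), n * 3L, replace = TRUE)
  pos <- as.integer(floor(runif(n * 3L) * lens[chrom]))
  key <- !duplicated(paste(chrom, pos))
  chrom <- chrom[key][seq_len(n)]; pos <- pos[key][seq_len(n)]
  seqs <- as.character(genomeSeqs(genome))
  ref <- substr(seqs[chrom], pos + 1L, pos + 1L)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
  VariantCatalog(cloneId, chrom = chrom, pos = pos, ref = ref, alt = alt,
                 genome = genome)
}

## per-clone class counts printed in the study's summary table (the seven
## cleanly tokenised clones), used to reconstruct catalogs for consistency
## checks
TABLE1_COUNTS <- list(
  "ANC-1"  = c(254, 63, 175, 48, 206, 57, 66),
  "ANC-2"  = c(241, 69, 169, 38, 214, 43, 73),
  "AN21-1" = c(5612, 718, 371, 167, 817, 98, 113),
  "AN21-2" = c(3597, 399, 275, 40, 185, 46, 63),
  "HK34"   = c(2086, 59, 71, 10, 23, 6, 45),
  "RF23M"  = c(437, 41, 69, 5, 9, 12, 26),
  "RF24M"  = c(1573, 96, 76, 13, 15, 7, 33))
TABLE1_TOTALS <- c("ANC-1" = 869, "ANC-2" = 847, "AN21-1" = 7896,
                   "AN21-2" = 4605, "HK34" = 2300, "RF23M" = 599,
                   "RF24M" = 1813)
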