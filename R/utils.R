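## internal helpers shared across modules

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.revcompChar <- function(x) {
  # vectorised reverse complement for plain character vectors
  as.character(reverseComplement(DNAStringSet(x)))
}

.variantKind <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  kind <- rep("MNV", length(ref))
  kind[nr == 1L & na == 1L] <- "SNV"
  kind[na > nr] <- "insertion"
  kind[na < nr] <- "deletion"
  kind
}

.variantKey <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

.checkBases <- function(x, what = "allele") {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad))
    stop(sprintf("%s must contain only A/C/G/T (offending: %s)", what,
                 paste(utils::head(unique(x[bad]), 5), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

.chromSeq <- function(genome, chrom) {
  i <- match(chrom, names(genome@seqs))
  if (is.na(i))
    stop(sprintf("chromosome '%s' not present in genome (names are matched %s",
                 chrom, "exactly; no 'chr' aliasing)"), call. = FALSE)
  genome@seqs[[i]]
}

## round half up to `digits` decimals (base round() rounds half to even)
.roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## deterministic sub-seed derivation, kept inside 32-bit integer range
.subSeed <- function(seed, k) as.integer((as.numeric(seed) + 7919 * k) %% .Machine$integer.max)
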