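#' Read a reference genome from FASTA
#'
#' Reads a multi-record FASTA into a [Genome-class] object. Sequences are
#' normalised to uppercase; any soft-masked (lowercase) stretches are
#' recorded in the genome's mask track. Only A/C/G/T/N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A [Genome-class].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTNACGT"), fa)
#' g <- readGenomeFasta(fa)
#' chromLengths(g)
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L)
    stop("FASTA file ", path, " contains no records", call. = FALSE)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm))
    stop("duplicate chromosome record(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  chr <- as.character(raw)
  badChar <- grepl("[^ACGTNacgtn]", chr)
  if (any(badChar)) {
    ln <- .fastaBadLine(path)
    stop(sprintf("invalid sequence character in %s (record '%s', line %d)",
                 path, nm[which(badChar)[1L]], ln), call. = FALSE)
  }
  mask <- list()
  hasLower <- grepl("[acgtn]", chr)
  for (i in which(hasLower)) {
    m <- gregexpr("[acgtn]+", chr[i])[[1L]]
    mask[[nm[i]]] <- IRanges(start = as.integer(m),
                             width = attr(m, "match.length"))
  }
  seqs <- DNAStringSet(toupper(chr))
  names(seqs) <- nm
  new("Genome", seqs = seqs, mask = mask)
}

## first file line whose sequence content has a character outside A/C/G/T/N
.fastaBadLine <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (startsWith(l, ">")) next
    if (grepl("[^ACGTNacgtn[:space:]]", l)) return(i)
  }
  NA_integer_
}

#' Construct a Genome from in-memory sequences
#'
#' @param seqs Named character vector or \link[Biostrings]{DNAStringSet} of
#'   chromosome sequences (A/C/G/T/N; lowercase is uppercased).
#' @return A [Genome-class].
#' @export
#' @examples
#' Genome(c(chr1 = "ACGTACGT"))
Genome <- function(seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
  new("Genome", seqs = seqs, mask = list())
}

#' Write a Genome to FASTA
#'
#' @param genome A [Genome-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome@seqs, path)
  invisible(path)
}

#' Construct a variant catalog
#'
#' Builds a [VariantCatalog-class] from parallel vectors, normalising case,
#' classifying each variant (SNV / insertion / deletion / MNV), sorting by
#' (chrom, pos, ref, alt) and rejecting duplicates. If a genome is supplied,
#' every reference allele is checked against it.
#'
#' @param cloneId Clone label.
#' @param chrom,pos,ref,alt Parallel vectors; \code{pos} is the 0-based
#'   position of the first reference base.
#' @param genome Optional [Genome-class] for reference-allele verification.
#' @param provenance Free-text origin note.
#' @return A [VariantCatalog-class].
#' @export
#' @examples
#' VariantCatalog("cl1", chrom = c("chr1", "chr1"), pos = c(4L, 9L),
#'                ref = c("C", "G"), alt = c("T", "A"))
VariantCatalog <- function(cloneId, chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           genome = NULL, provenance = "") {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  chrom <- as.character(chrom); pos <- as.integer(pos)
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), length(pos) == length(ref),
            length(ref) == length(alt))
  if (length(chrom)) {
    .checkBases(ref, "ref allele"); .checkBases(alt, "alt allele")
    if (any(ref == alt))
      stop("ref and alt alleles must differ", call. = FALSE)
  }
  v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  kind = .variantKind(ref, alt), stringsAsFactors = FALSE)
  v <- v[order(v$chrom, v$pos, v$ref, v$alt, method = "radix"), , drop = FALSE]
  rownames(v) <- NULL
  if (!is.null(genome)) .verifyRefAlleles(v, genome)
  new("VariantCatalog", cloneId = as.character(cloneId), variants = v,
      provenance = provenance)
}

.verifyRefAlleles <- function(v, genome) {
  if (!nrow(v)) return(invisible(TRUE))
  bad <- character()
  for (ch in unique(v$chrom)) {
    s <- .chromSeq(genome, ch)
    idx <- which(v$chrom == ch)
    for (i in idx) {
      from <- v$pos[i] + 1L
      to <- v$pos[i] + nchar(v$ref[i])
      if (to > length(s)) { bad <- c(bad, .variantKey(v[i, ])); next }
      obs <- as.character(Biostrings::subseq(s, from, to))
      if (obs != v$ref[i]) bad <- c(bad, .variantKey(v[i, ]))
    }
  }
  if (length(bad))
    stop("reference allele mismatch vs genome at: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  invisible(TRUE)
}

#' Read variants from a VCF file
#'
#' Reads VCF 4.x, converts 1-based positions to the internal 0-based
#' convention, splits multi-allelic records into biallelic variants, and
#' (optionally) verifies reference alleles against a genome. Records with
#' non-A/C/G/T alleles (symbolic alleles, breakends, IUPAC codes) are skipped
#' with a warning giving the number skipped.
#'
#' @param path Path to a VCF file.
#' @param genome Optional [Genome-class]; when supplied every ref allele is
#'   verified and mismatches are an error.
#' @param cloneId Clone label; defaults to the file name without extension.
#' @return A [VariantCatalog-class].
#' @export
readVariantVcf <- function(path, genome = NULL, cloneId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(cloneId))
    cloneId <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- VariantAnnotation::readVcf(path, genome = "unspecified")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  ok <- grepl("^[ACGTacgt]+$", ref) & grepl("^[ACGTacgt]+$", alt)
  nSkip <- sum(!ok)
  if (nSkip > 0L)
    warning(nSkip, " record(s) with non-A/C/G/T alleles skipped",
            call. = FALSE)
  VariantCatalog(cloneId, chrom = chrom[ok], pos = pos1[ok] - 1L,
                 ref = ref[ok], alt = alt[ok], genome = genome,
                 provenance = paste0("read from ", basename(path)))
}

#' Write a variant catalog to VCF 4.2
#'
#' Positions are written 1-based per the VCF standard. When a genome is
#' supplied, contig header lines carry chromosome lengths and any catalog
#' chromosome absent from the genome is an error.
#'
#' @param catalog A [VariantCatalog-class].
#' @param path Output path.
#' @param genome Optional [Genome-class] used for contig lengths.
#' @return Invisibly, \code{path}.
#' @export
writeVariantVcf <- function(catalog, path, genome = NULL) {
  v <- catalog@variants
  chroms <- unique(v$chrom)
  if (!is.null(genome)) {
    missing <- setdiff(chroms, chromNames(genome))
    if (length(missing))
      stop("catalog chromosome(s) not in genome: ",
           paste(missing, collapse = ", "), call. = FALSE)
    contig <- DataFrame(length = unname(chromLengths(genome)[chroms]),
                        row.names = chroms)
  } else {
    contig <- DataFrame(length = rep(NA_integer_, length(chroms)),
                        row.names = chroms)
  }
  n <- nrow(v)
  gr <- GenomicRanges::GRanges(v$chrom,
                               IRanges(start = v$pos + 1L,
                                       width = nchar(v$ref)))
  names(gr) <- rep(".", n)
  fx <- DataFrame(REF = DNAStringSet(v$ref), ALT = DNAStringSet(v$alt),
                  QUAL = rep(NA_real_, n), FILTER = rep(".", n))
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fx, collapsed = FALSE)
  hdr <- VariantAnnotation::VCFHeader(samples = character(0))
  VariantAnnotation::meta(hdr)$fileformat <-
    DataFrame(Value = "VCFv4.2", row.names = "fileformat")
  VariantAnnotation::meta(hdr)$contig <- contig
  metadata(vcf)$header <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read a paired clone/parental allele-count table
#'
#' Reads the tab-delimited per-site read-count format with header columns
#' \code{chrom, pos, ref, alt, t_ref, t_alt, n_ref, n_alt} (\code{pos}
#' 1-based in the file; \code{t_*} are clone/"tumor" counts, \code{n_*}
#' parental/"normal" counts). Lines starting with '#' are comments.
#' Positions are converted to the internal 0-based convention.
#'
#' @param path Path to the TSV.
#' @param indelStyle \code{"anchored"} (VCF-style shared first base, the
#'   default) or \code{"plusminus"}, in which indel alt alleles are written
#'   \code{"+SEQ"} / \code{"-SEQ"} relative to a single-base ref and are
#'   converted to anchored form on read.
#' @return A data.frame with columns \code{chrom, pos, ref, alt, tRef, tAlt,
#'   nRef, nAlt}; \code{pos} 0-based.
#' @export
readCountsTable <- function(path, indelStyle = c("anchored", "plusminus")) {
  indelStyle <- match.arg(indelStyle)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "n_ref", "n_alt")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("counts table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cnt <- c("t_ref", "t_alt", "n_ref", "n_alt")
  for (cc in cnt) {
    if (!is.numeric(df[[cc]]))
      stop("column ", cc, " must be numeric", call. = FALSE)
    if (any(df[[cc]] < 0))
      stop("negative count in column ", cc, call. = FALSE)
  }
  ref <- toupper(df$ref); alt <- toupper(df$alt)
  if (indelStyle == "plusminus") {
    ins <- startsWith(alt, "+"); del <- startsWith(alt, "-")
    alt[ins] <- paste0(ref[ins], sub("^\\+", "", alt[ins]))
    newRef <- paste0(ref[del], sub("^-", "", alt[del]))
    alt[del] <- ref[del]
    ref[del] <- newRef
  }
  .checkBases(ref, "ref allele"); .checkBases(alt, "alt allele")
  out <- data.frame(chrom = as.character(df$chrom),
                    pos = as.integer(df$pos) - 1L,
                    ref = ref, alt = alt,
                    tRef = as.integer(df$t_ref), tAlt = as.integer(df$t_alt),
                    nRef = as.integer(df$n_ref), nAlt = as.integer(df$n_alt),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a paired allele-count table
#'
#' Inverse of [readCountsTable()]; positions are written 1-based.
#'
#' @param counts Data.frame as returned by [readCountsTable()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCountsTable <- function(counts, path) {
  out <- data.frame(chrom = counts$chrom, pos = counts$pos + 1L,
                    ref = counts$ref, alt = counts$alt,
                    t_ref = counts$tRef, t_alt = counts$tAlt,
                    n_ref = counts$nRef, n_alt = counts$nAlt)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predicted CRISPR off-target site table
#'
#' Tab-delimited, BED-compatible in its first three columns: \code{chrom},
#' \code{start}, \code{end} (0-based half-open interval covering
#' protospacer + PAM), then \code{gRNA}, \code{mismatches} and \code{cfd}
#' (Cutting Frequency Determination score in [0, 1]). Row order is
#' preserved, so a list ordered by descending CFD score round-trips.
#'
#' @param path Path to the TSV.
#' @return Data.frame with those six columns.
#' @export
readOffTargetSites <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gRNA", "mismatches", "cfd")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("off-target table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$start >= df$end))
    stop("off-target sites must satisfy start < end", call. = FALSE)
  if (any(df$mismatches < 0)) stop("mismatches must be >= 0", call. = FALSE)
  if (any(df$cfd < 0 | df$cfd > 1))
    stop("cfd scores must lie in [0, 1]", call. = FALSE)
  df[need]
}

#' Write an off-target site table
#'
#' @param sites Data.frame as returned by [readOffTargetSites()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeOffTargetSites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
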