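#' Construct a context window
#'
#' @param upstream Positions kept 5' of the mutated base on its oriented
#'   strand (>= 1). Default 5.
#' @param downstream Positions kept 3' (>= 1). Default 25.
#' @return A [ContextWindow-class].
#' @export
#' @examples
#' contextWindow()        # the -5..+25 logo window
#' contextWindow(1, 1)    # trinucleotide context
contextWindow <- function(upstream = 5L, downstream = 25L) {
  new("ContextWindow", upstream = as.integer(upstream),
      downstream = as.integer(downstream))
}

#' Extract strand-oriented flanking contexts around mutated cytosines
#'
#' For every eligible SNV at a C:G site, reads the window
#' \code{-upstream..+downstream} on the strand where the mutated base reads
#' C: variants with \code{ref == "C"} are read on the plus strand, variants
#' with \code{ref == "G"} on the reverse complement, so that "downstream"
#' is always 3' of the deaminated cytosine. Windows that run off the
#' chromosome or overlap an N are excluded (never padded) and counted by
#' reason.
#'
#' @param catalog A [VariantCatalog-class].
#' @param genome A [Genome-class]; reference alleles must match it.
#' @param window A [ContextWindow-class]; default [contextWindow()].
#' @param classes Which substitution classes to include; default
#'   \code{"C:G>T:A"}. Only C:G classes are meaningful here.
#' @return An [OrientedContextSet-class].
#' @export
#' @examples
#' g <- Genome(c(chr1 = "AATCAGG"))
#' cat <- VariantCatalog("demo", "chr1", 3L, "C", "T")
#' as.character(contexts(extractContexts(cat, g, contextWindow(1, 1))))
extractContexts <- function(catalog, genome, window = contextWindow(),
                            classes = "C:G>T:A") {
  stopifnot(is(catalog, "VariantCatalog"), is(genome, "Genome"),
            is(window, "ContextWindow"))
  v <- catalog@variants
  v <- v[v$kind == "SNV" & v$ref %in% c("C", "G"), , drop = FALSE]
  if (nrow(v)) {
    cls <- classifySubstitution(v$ref, v$alt)
    v <- v[cls %in% classes, , drop = FALSE]
  }
  up <- window@upstream; dn <- window@downstream
  excl <- c(out_of_bounds = 0L, contains_n = 0L)
  seqsOut <- character(0)
  for (ch in unique(v$chrom)) {
    s <- .chromSeq(genome, ch)
    len <- length(s)
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]; isC <- v$ref[idx] == "C"
    # verify the genome agrees with the catalog's ref alleles
    refObs <- as.character(Views(s, start = pos + 1L, end = pos + 1L))
    if (!all(refObs == v$ref[idx]))
      stop("reference allele mismatch vs genome on ", ch, call. = FALSE)
    from <- ifelse(isC, pos + 1L - up, pos + 1L - dn)
    to <- ifelse(isC, pos + 1L + dn, pos + 1L + up)
    inb <- from >= 1L & to <= len
    excl["out_of_bounds"] <- excl["out_of_bounds"] + sum(!inb)
    if (!any(inb)) next
    win <- DNAStringSet(Views(s, start = from[inb], end = to[inb]))
    win[!isC[inb]] <- reverseComplement(win[!isC[inb]])
    hasN <- grepl("N", as.character(win), fixed = TRUE)
    excl["contains_n"] <- excl["contains_n"] + sum(hasN)
    seqsOut <- c(seqsOut, as.character(win)[!hasN])
  }
  new("OrientedContextSet", contexts = DNAStringSet(seqsOut),
      upstream = up, downstream = dn, excluded = excl)
}

#' Build a position frequency matrix and information-content profile
#'
#' Column-wise relative base frequencies over a set of equal-width oriented
#' contexts, with per-position information content 2 - H bits (H the
#' Shannon entropy of the column, 0 log 0 taken as 0) -- the quantities a
#' sequence logo displays. The optional small-sample correction subtracts
#' e(n) = 3 / (2 n ln 2) from every position's information content (floored
#' at zero); it is off by default since context sets here are typically in
#' the hundreds to thousands.
#'
#' @param x An [OrientedContextSet-class], or a character vector /
#'   \link[Biostrings]{DNAStringSet} of equal-width sequences (in which case
#'   \code{upstream} gives the 0-position).
#' @param correction \code{"none"} (default) or \code{"small_sample"}.
#' @param upstream Only used when \code{x} is not an
#'   [OrientedContextSet-class].
#' @return A [ContextMatrix-class].
#' @export
#' @examples
#' cm <- buildContextMatrix(c("TCA", "TCT", "TCA", "GCA"), upstream = 1)
#' infoBits(cm)
buildContextMatrix <- function(x, correction = c("none", "small_sample"),
                               upstream = NULL) {
  correction <- match.arg(correction)
  if (is(x, "OrientedContextSet")) {
    upstream <- x@upstream
    x <- x@contexts
  }
  if (is.character(x)) x <- DNAStringSet(x)
  if (length(x) < 1L) stop("need at least one context", call. = FALSE)
  if (length(unique(Biostrings::width(x))) != 1L)
    stop("contexts must all have the same length", call. = FALSE)
  if (is.null(upstream))
    stop("upstream must be given for raw sequence input", call. = FALSE)
  n <- length(x)
  L <- Biostrings::width(x)[1L]
  cm <- consensusMatrix(x)[c("A", "C", "G", "T"), , drop = FALSE]
  freq <- sweep(cm, 2L, colSums(cm), "/")
  H <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  info <- 2 - H
  if (correction == "small_sample")
    info <- pmax(0, info - 3 / (2 * log(2) * n))
  new("ContextMatrix", positions = seq_len(L) - as.integer(upstream) - 1L,
      freq = freq, infoBits = unname(info), n = as.integer(n))
}

#' Fraction of contexts matching the TCW motif
#'
#' The APOBEC signature motif: T immediately 5' of the mutated C and W (A
#' or T) immediately 3', on the oriented strand.
#'
#' @param x An [OrientedContextSet-class] with at least one position on each
#'   side of the centre.
#' @return Fraction in [0, 1].
#' @export
tcwFraction <- function(x) {
  stopifnot(is(x, "OrientedContextSet"))
  if (x@upstream < 1L || x@downstream < 1L)
    stop("window too small: need positions -1 and +1", call. = FALSE)
  if (!length(x@contexts)) stop("no contexts to evaluate", call. = FALSE)
  ctr <- x@upstream + 1L
  m1 <- as.character(Biostrings::subseq(x@contexts, ctr - 1L, ctr - 1L))
  p1 <- as.character(Biostrings::subseq(x@contexts, ctr + 1L, ctr + 1L))
  mean(m1 == "T" & p1 %in% c("A", "T"))
}

#' TCW-motif enrichment of a catalog over its genome background
#'
#' Compares the fraction of mutated cytosines (C:G>T:A and C:G>G:C SNVs)
#' sitting in a TCW trinucleotide context against the fraction of all
#' genomic cytosines -- counted on both strands of the analysed genome
#' itself -- whose context is TCW. Cytosines lacking a complete N-free
#' trinucleotide context (chromosome ends, N-adjacent) are excluded from
#' the background denominator, matching the exclusion rule used for
#' observed contexts.
#'
#' @param catalog A [VariantCatalog-class] with at least one C:G>T:A or
#'   C:G>G:C SNV.
#' @param genome A [Genome-class].
#' @param window A [ContextWindow-class] used for context extraction;
#'   default trinucleotide (\code{contextWindow(1, 1)}).
#' @param classes Substitution classes considered; default both C:G>T:A and
#'   C:G>G:C.
#' @return List with \code{observedFraction}, \code{backgroundFraction},
#'   \code{enrichmentRatio}, \code{pValue} (one-sided exact binomial test of
#'   the observed TCW count against the background fraction), \code{nObserved}
#'   (evaluated contexts) and \code{nTcw}.
#' @export
tcwEnrichment <- function(catalog, genome, window = contextWindow(1L, 1L),
                          classes = c("C:G>T:A", "C:G>G:C")) {
  octx <- extractContexts(catalog, genome, window = window, classes = classes)
  n <- length(octx@contexts)
  if (n == 0L) stop("no eligible C:G contexts in catalog", call. = FALSE)
  obsFrac <- tcwFraction(octx)
  nTcw <- round(obsFrac * n)
  bg <- .tcwBackground(genome)
  ratio <- if (bg > 0) obsFrac / bg else NA_real_
  p <- stats::binom.test(nTcw, n, p = bg, alternative = "greater")$p.value
  list(observedFraction = obsFrac, backgroundFraction = bg,
       enrichmentRatio = ratio, pValue = p, nObserved = n, nTcw = nTcw)
}

## genome-wide fraction of cytosines (both strands) in TCW context,
## computed from trinucleotide counts (N-containing windows drop out)
.tcwBackground <- function(genome) {
  tri <- oligonucleotideFrequency(genome@seqs, width = 3L)
  tot <- colSums(tri)
  mid <- substr(names(tot), 2L, 2L)
  denom <- sum(tot[mid %in% c("C", "G")])
  if (denom == 0) stop("genome has no C:G trinucleotides", call. = FALSE)
  num <- sum(tot[c("TCA", "TCT", "TGA", "AGA")])
  num / denom
}

#' Write a context matrix as TSV
#'
#' Columns: position, fA, fC, fG, fT, bits.
#'
#' @param cm A [ContextMatrix-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeContextMatrix <- function(cm, path) {
  df <- data.frame(position = cm@positions,
                   fA = cm@freq["A", ], fC = cm@freq["C", ],
                   fG = cm@freq["G", ], fT = cm@freq["T", ],
                   bits = cm@infoBits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write oriented contexts as FASTA
#'
#' The format consumed by common sequence-logo renderers.
#'
#' @param octx An [OrientedContextSet-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeContextsFasta <- function(octx, path) {
  s <- octx@contexts
  names(s) <- paste0("context_", seq_along(s))
  writeXStringSet(s, path)
  invisible(path)
}
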