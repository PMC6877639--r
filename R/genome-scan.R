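#' Does a 6-base window contain an NGG PAM?
#'
#' A window is positive iff some trinucleotide N-G-G lies fully within it,
#' i.e. a GG dinucleotide starts at one of the last five positions but not
#' the final one (NGG start offsets 0..3 within the window). Only the given
#' strand is searched; the reverse-strand CCN motif is deliberately not
#' counted.
#'
#' @param x Character vector (or \link[Biostrings]{DNAStringSet}) of 6-base
#'   windows over A/C/G/T.
#' @return Logical vector.
#' @export
#' @examples
#' containsNgg(c("TAGGAC", "ACACAC"))
containsNgg <- function(x) {
  if (is(x, "XStringSet")) x <- as.character(x)
  x <- toupper(x)
  if (any(nchar(x) != 6L))
    stop("PAM windows must be exactly 6 bases", call. = FALSE)
  .checkBases(x, "PAM window")
  grepl("GG", substr(x, 2L, 6L), fixed = TRUE)
}

#' PAM proximity of mutated cytosines
#'
#' For every C:G SNV in the catalog, tests whether the 6 bases at distances
#' 15..20 downstream of the mutated cytosine contain an NGG PAM.
#' "Downstream" is 3' of the mutated base on the strand where it reads C
#' (the same orientation rule as context extraction); pass
#' \code{orientation = "reference"} to instead always read the plus strand.
#' Windows running off the chromosome or containing N are excluded and
#' counted.
#'
#' @param catalog A [VariantCatalog-class]; only C:G SNVs are evaluated.
#' @param genome A [Genome-class].
#' @param offsetStart,offsetEnd 1-based distances downstream delimiting the
#'   window (defaults 15 and 20, a 6-base window).
#' @param orientation \code{"mutated_c"} (default) or \code{"reference"}.
#' @return List with \code{fraction} (windows containing NGG / evaluated),
#'   \code{nEvaluated} and \code{nExcluded}.
#' @export
pamProximityFraction <- function(catalog, genome, offsetStart = 15L,
                                 offsetEnd = 20L,
                                 orientation = c("mutated_c", "reference")) {
  orientation <- match.arg(orientation)
  stopifnot(is(catalog, "VariantCatalog"), is(genome, "Genome"))
  if (offsetEnd - offsetStart + 1L != 6L)
    stop("the PAM window must span 6 bases", call. = FALSE)
  v <- catalog@variants
  v <- v[v$kind == "SNV" & v$ref %in% c("C", "G"), , drop = FALSE]
  if (!nrow(v)) stop("no C:G SNVs to evaluate", call. = FALSE)
  wins <- character(0)
  nExcluded <- 0L
  for (ch in unique(v$chrom)) {
    s <- .chromSeq(genome, ch)
    len <- length(s)
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]
    plus <- if (orientation == "reference") rep(TRUE, length(idx))
            else v$ref[idx] == "C"
    from <- ifelse(plus, pos + 1L + offsetStart, pos + 1L - offsetEnd)
    to <- ifelse(plus, pos + 1L + offsetEnd, pos + 1L - offsetStart)
    inb <- from >= 1L & to <= len
    nExcluded <- nExcluded + sum(!inb)
    if (!any(inb)) next
    w <- DNAStringSet(Views(s, start = from[inb], end = to[inb]))
    w[!plus[inb]] <- reverseComplement(w[!plus[inb]])
    wc <- as.character(w)
    hasN <- grepl("N", wc, fixed = TRUE)
    nExcluded <- nExcluded + sum(hasN)
    wins <- c(wins, wc[!hasN])
  }
  if (!length(wins))
    stop("no evaluable PAM windows (all excluded)", call. = FALSE)
  list(fraction = mean(containsNgg(wins)), nEvaluated = length(wins),
       nExcluded = nExcluded)
}

#' Genome-wide background NGG frequency from sampled windows
#'
#' Draws \code{nSamples} 6-base windows uniformly over all valid start
#' positions genome-wide (in-bounds and N-free; chromosomes weighted by
#' their number of valid starts) with a seeded generator, and reports the
#' fraction containing an NGG PAM together with its binomial standard
#' error.
#'
#' @param genome A [Genome-class] with at least one N-free run of window
#'   length.
#' @param nSamples Number of windows to draw; default 1e6.
#' @param windowLength Window width; default 6.
#' @param seed Optional integer seed for reproducibility.
#' @return List with \code{fraction}, \code{se} and \code{nSamples}.
#' @export
backgroundPamFrequency <- function(genome, nSamples = 1e6, windowLength = 6L,
                                   seed = NULL) {
  stopifnot(is(genome, "Genome"))
  if (nSamples < 1) stop("nSamples must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lens <- chromLengths(genome)
  keep <- lens >= windowLength
  if (!any(keep)) stop("no chromosome long enough for a window", call. = FALSE)
  valid <- lapply(names(lens)[keep], function(ch) {
    s <- .chromSeq(genome, ch)
    nStarts <- length(s) - windowLength + 1L
    nPos <- Biostrings::start(matchPattern("N", s))
    if (!length(nPos)) return(list(n = nStarts, bad = integer(0)))
    bad <- unique(unlist(lapply(nPos, function(p)
      max(1L, p - windowLength + 1L):min(nStarts, p))))
    list(n = nStarts - length(bad), bad = sort(bad))
  })
  names(valid) <- names(lens)[keep]
  nValid <- vapply(valid, `[[`, numeric(1), "n")
  if (sum(nValid) == 0)
    stop("no valid (N-free) window positions in genome", call. = FALSE)
  # sample chromosome by valid-start weight, then index within valid starts
  chSel <- sample.int(length(nValid), nSamples, replace = TRUE,
                      prob = nValid / sum(nValid))
  hits <- 0
  for (ci in unique(chSel)) {
    ch <- names(valid)[ci]
    k <- sum(chSel == ci)
    vi <- valid[[ci]]
    ix <- sample.int(vi$n, k, replace = TRUE)
    if (length(vi$bad)) {
      # map index among valid starts to an actual start position
      allStarts <- setdiff(seq_len(vi$n + length(vi$bad)), vi$bad)
      starts <- allStarts[ix]
    } else starts <- ix
    sChar <- as.character(.chromSeq(genome, ch))
    w <- substring(sChar, starts, starts + windowLength - 1L)
    hits <- hits + sum(containsNgg(w))
  }
  f <- hits / nSamples
  list(fraction = f, se = sqrt(f * (1 - f) / nSamples),
       nSamples = as.integer(nSamples))
}

#' Intersect a variant catalog with predicted off-target sites
#'
#' A variant hits a site iff the 0-based position of its first reference
#' base lies in the half-open interval \code{[start - flank, end + flank)}.
#' Returns per-site variant counts ordered by descending CFD score plus the
#' total number of hits.
#'
#' @param catalog A [VariantCatalog-class].
#' @param sites Off-target site data.frame as from [readOffTargetSites()].
#' @param flank Extra bases added on each side of every site; default 0.
#' @return List with \code{perSite} (the site table plus an
#'   \code{nVariants} column, sorted by descending \code{cfd}) and
#'   \code{total}.
#' @export
#' @examples
#' cat <- VariantCatalog("demo", "chr1", 100L, "C", "T")
#' sites <- data.frame(chrom = "chr1", start = 90L, end = 113L,
#'                     gRNA = "HEK3", mismatches = 2L, cfd = 0.5)
#' intersectOffTargets(cat, sites)$total
intersectOffTargets <- function(catalog, sites, flank = 0L) {
  stopifnot(is(catalog, "VariantCatalog"))
  sites <- sites[order(-sites$cfd), , drop = FALSE]
  rownames(sites) <- NULL
  if (!nrow(sites))
    return(list(perSite = cbind(sites, nVariants = integer(0)), total = 0L))
  v <- catalog@variants
  if (!nrow(v)) {
    sites$nVariants <- 0L
    return(list(perSite = sites, total = 0L))
  }
  # half-open [start - flank, end + flank) in 0-based = closed 1-based
  siteGr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges(start = sites$start - flank + 1L,
                                           end = sites$end + flank))
  varGr <- GenomicRanges::GRanges(v$chrom, IRanges(start = v$pos + 1L,
                                                   width = 1L))
  sites$nVariants <- GenomicRanges::countOverlaps(siteGr, varGr)
  list(perSite = sites, total = sum(sites$nVariants))
}
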