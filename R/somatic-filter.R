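#' Construct somatic filter thresholds
#'
#' The filtering criteria applied to paired clone/parental calls: Fisher
#' p-value < \code{maxP}, parental VAF < \code{maxNormalVaf}, clone VAF >
#' \code{minTumorVaf} and clone alt-supporting reads > \code{minTumorAltReads}
#' (all strict inequalities).
#'
#' @param maxP Maximum Fisher p-value (exclusive). Default 0.001.
#' @param maxNormalVaf Maximum parental variant allele frequency (exclusive).
#'   Default 0.05.
#' @param minTumorVaf Minimum clone variant allele frequency (exclusive).
#'   Default the exact fraction 1/3; pass 0.3333 for the printed constant.
#' @param minTumorAltReads Minimum clone alt read count (exclusive, i.e. a
#'   site needs strictly more than this many supporting reads). Default 6.
#' @return A [FilterThresholds-class].
#' @export
#' @examples
#' filterThresholds()
filterThresholds <- function(maxP = 0.001, maxNormalVaf = 0.05,
                             minTumorVaf = 1 / 3, minTumorAltReads = 6) {
  new("FilterThresholds", maxP = maxP, maxNormalVaf = maxNormalVaf,
      minTumorVaf = minTumorVaf, minTumorAltReads = minTumorAltReads)
}

#' Paired Fisher exact test for clone/parental allele counts
#'
#' One-sided Fisher exact test on the 2x2 table
#' \code{[[tAlt, tRef], [nAlt, nRef]]} against the alternative that the
#' clone's ("tumor") alt allele fraction exceeds the parental ("normal")
#' one. The one-sided p-value is the hypergeometric upper tail
#' P(X >= tAlt) with the table's margins fixed. A two-sided variant is
#' available for sensitivity analysis.
#'
#' @param tAlt,tRef Clone alt / ref read counts (vectorised).
#' @param nAlt,nRef Parental alt / ref read counts.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' fisherSomaticP(tAlt = 5, tRef = 5, nAlt = 0, nRef = 10)
#' fisherSomaticP(tAlt = 0, tRef = 10, nAlt = 0, nRef = 10)  # 1
fisherSomaticP <- function(tAlt, tRef, nAlt, nRef,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(tAlt), length(tRef), length(nAlt), length(nRef))
  tAlt <- rep_len(tAlt, n); tRef <- rep_len(tRef, n)
  nAlt <- rep_len(nAlt, n); nRef <- rep_len(nRef, n)
  if (any(c(tAlt, tRef, nAlt, nRef) < 0))
    stop("read counts must be >= 0", call. = FALSE)
  if (any(tAlt + tRef == 0) || any(nAlt + nRef == 0))
    stop("zero depth in tumor or normal sample", call. = FALSE)
  if (alternative == "greater") {
    # hypergeometric upper tail: draws = tumor depth, white = total alt
    p <- phyper(tAlt - 1, m = tAlt + nAlt, n = tRef + nRef,
                k = tAlt + tRef, lower.tail = FALSE)
    return(pmin(p, 1))
  }
  vapply(seq_len(n), function(i)
    stats::fisher.test(matrix(c(tAlt[i], tRef[i], nAlt[i], nRef[i]),
                              nrow = 2, byrow = TRUE),
                       alternative = "two.sided")$p.value,
    numeric(1))
}

#' Filter paired allele counts into a somatic variant catalog
#'
#' Applies the Fisher exact test and the four threshold criteria to every
#' site. A site is retained iff all four strict criteria hold; every
#' rejected site carries the complete set of failed criteria. Sites with no
#' alt evidence in the clone are evaluated normally (p = 1), keeping the
#' filter total over its input.
#'
#' @param sites Data.frame of paired counts as from [readCountsTable()] or
#'   [simulateCounts()].
#' @param thresholds A [FilterThresholds-class]; default [filterThresholds()].
#' @param cloneId Label for the emitted catalog.
#' @param genome Optional [Genome-class] for ref-allele verification of the
#'   retained calls.
#' @param alternative Sidedness of the Fisher test, see [fisherSomaticP()].
#' @return A list with elements \code{catalog} (a sorted
#'   [VariantCatalog-class] of retained calls) and \code{calls} (per-site
#'   audit data.frame with p-value, both VAFs, verdict, and semicolon-joined
#'   rejection reasons drawn from \code{p, normal_vaf, tumor_vaf,
#'   alt_reads}).
#' @export
#' @examples
#' s <- data.frame(chrom = "chr1", pos = 99L, ref = "C", alt = "T",
#'                 tRef = 12L, tAlt = 12L, nRef = 30L, nAlt = 0L)
#' filterSomatic(s, cloneId = "demo")$calls
filterSomatic <- function(sites, thresholds = filterThresholds(),
                          cloneId = "clone", genome = NULL,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is(thresholds, "FilterThresholds"))
  validObject(thresholds)
  need <- c("chrom", "pos", "ref", "alt", "tRef", "tAlt", "nRef", "nAlt")
  missing <- setdiff(need, names(sites))
  if (length(missing))
    stop("sites missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- fisherSomaticP(sites$tAlt, sites$tRef, sites$nAlt, sites$nRef,
                      alternative = alternative)
  tumorVaf <- sites$tAlt / (sites$tAlt + sites$tRef)
  normalVaf <- sites$nAlt / (sites$nAlt + sites$nRef)
  fail <- cbind(p = !(p < thresholds@maxP),
                normal_vaf = !(normalVaf < thresholds@maxNormalVaf),
                tumor_vaf = !(tumorVaf > thresholds@minTumorVaf),
                alt_reads = !(sites$tAlt > thresholds@minTumorAltReads))
  retained <- rowSums(fail) == 0L
  reasons <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = ";"))
  calls <- data.frame(sites[need],
                      pValue = p, tumorVaf = tumorVaf, normalVaf = normalVaf,
                      verdict = ifelse(retained, "retained", "rejected"),
                      reasons = reasons, stringsAsFactors = FALSE)
  catalog <- VariantCatalog(cloneId,
                            chrom = sites$chrom[retained],
                            pos = sites$pos[retained],
                            ref = sites$ref[retained],
                            alt = sites$alt[retained],
                            genome = genome,
                            provenance = "somatic filter on paired counts")
  list(catalog = catalog, calls = calls)
}

#' Write the per-site somatic filter audit table
#'
#' Positions are written 1-based to match the input count-table convention.
#'
#' @param calls The \code{calls} element of a [filterSomatic()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFilterAudit <- function(calls, path) {
  out <- calls
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
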