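## pyrimidine-normalised substitution class lookup: key = paste0(ref, alt)
.CLASS_LOOKUP <- c(
  CT = "C:G>T:A", GA = "C:G>T:A",
  CG = "C:G>G:C", GC = "C:G>G:C",
  CA = "C:G>A:T", GT = "C:G>A:T",
  AC = "A:T>C:G", TG = "A:T>C:G",
  AG = "A:T>G:C", TC = "A:T>G:C",
  AT = "A:T>T:A", TA = "A:T>T:A")

#' Classify a single-base substitution
#'
#' Maps a ref/alt base pair to its pyrimidine-normalised class, so a
#' substitution and its strand complement land in the same class (e.g. both
#' C>T and G>A are \code{"C:G>T:A"}).
#'
#' @param ref,alt Single bases (vectorised), \code{ref != alt}.
#' @return Character vector of class labels among the six substitution
#'   classes of [mutationClasses()].
#' @export
#' @examples
#' classifySubstitution("C", "T")
#' classifySubstitution("G", "A")   # same class, opposite strand
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      !all(alt %in% c("A", "C", "G", "T")))
    stop("ref and alt must be single bases in {A,C,G,T}", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  unname(.CLASS_LOOKUP[paste0(ref, alt)])
}

#' Summarise a catalog into a mutation spectrum
#'
#' Counts every variant exactly once into the six substitution classes plus
#' the indel class. Multi-base substitutions (equal-length ref/alt longer
#' than one base) are decomposed into their differing positions and each
#' counted as an independent SNV, so they contribute one count per changed
#' base.
#'
#' @param catalog A [VariantCatalog-class].
#' @return A [SpectrumSummary-class].
#' @export
#' @examples
#' cat <- VariantCatalog("demo", chrom = "chr1", pos = 0:2,
#'                       ref = c("C", "G", "A"), alt = c("T", "A", "T"))
#' classCounts(summarizeCatalog(cat))
summarizeCatalog <- function(catalog) {
  v <- catalog@variants
  counts <- setNames(numeric(length(MUTATION_CLASSES)), MUTATION_CLASSES)
  if (nrow(v)) {
    snv <- v$kind == "SNV"
    mnv <- v$kind == "MNV"
    refs <- v$ref[snv]; alts <- v$alt[snv]
    if (any(mnv)) {
      for (i in which(mnv)) {
        rb <- strsplit(v$ref[i], "")[[1L]]
        ab <- strsplit(v$alt[i], "")[[1L]]
        diff <- rb != ab
        refs <- c(refs, rb[diff]); alts <- c(alts, ab[diff])
      }
    }
    if (length(refs)) {
      cls <- classifySubstitution(refs, alts)
      tb <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
      counts[SUBSTITUTION_CLASSES] <- as.numeric(tb)
    }
    counts["indel"] <- sum(v$kind %in% c("insertion", "deletion"))
  }
  new("SpectrumSummary", cloneId = catalog@cloneId, counts = counts,
      total = sum(counts))
}

#' Construct a spectrum summary directly from class counts
#'
#' Useful for working with published per-clone count tables when the
#' underlying variant list is not at hand.
#'
#' @param cloneId Clone label.
#' @param counts Numeric vector of length 7 in [mutationClasses()] order, or
#'   named by class.
#' @return A [SpectrumSummary-class].
#' @export
#' @examples
#' spectrumSummary("ANC-1", c(254, 63, 175, 48, 206, 57, 66))
spectrumSummary <- function(cloneId, counts) {
  if (is.null(names(counts))) {
    stopifnot(length(counts) == length(MUTATION_CLASSES))
    names(counts) <- MUTATION_CLASSES
  }
  counts <- counts[MUTATION_CLASSES]
  new("SpectrumSummary", cloneId = cloneId, counts = counts,
      total = sum(counts))
}

#' Percentage of a clone's mutations in one class
#'
#' @param summary A [SpectrumSummary-class] with total > 0.
#' @param class One of [mutationClasses()].
#' @param rounded If \code{TRUE}, round half-up to one decimal (the printed
#'   report precision); the default returns the unrounded percentage.
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' s <- spectrumSummary("HK34", c(2086, 59, 71, 10, 23, 6, 45))
#' typeFraction(s, "C:G>T:A", rounded = TRUE)
typeFraction <- function(summary, class, rounded = FALSE) {
  stopifnot(is(summary, "SpectrumSummary"))
  if (!class %in% MUTATION_CLASSES)
    stop("unknown mutation class: ", class, call. = FALSE)
  if (summary@total == 0) stop("summary has total 0", call. = FALSE)
  pct <- 100 * summary@counts[[class]] / summary@total
  if (rounded) .roundHalfUp(pct, 1L) else pct
}

#' Per-class fold change of a clone versus control clones
#'
#' For each mutation class, divides the clone's count by the arithmetic mean
#' of the control clones' counts for that class. A zero control mean yields
#' a flagged record with \code{NA} fold change rather than an infinity.
#'
#' @param cloneSummary A [SpectrumSummary-class] for the clone of interest.
#' @param controlSummaries Non-empty list of [SpectrumSummary-class] objects
#'   for the control clones (typically the procedure-control clones).
#' @return Data.frame with columns \code{cloneId}, \code{class},
#'   \code{cloneCount}, \code{controlMean}, \code{foldChange},
#'   \code{flagged}.
#' @export
#' @examples
#' hk34 <- spectrumSummary("HK34", c(2086, 59, 71, 10, 23, 6, 45))
#' ctrl <- list(spectrumSummary("N1", c(46, 6, 5, 3, 1, 4, 2)),
#'              spectrumSummary("N2", c(42, 3, 6, 6, 5, 1, 2)),
#'              spectrumSummary("N3", c(39, 4, 3, 6, 7, 1, 2)))
#' foldChanges(hk34, ctrl)
foldChanges <- function(cloneSummary, controlSummaries) {
  stopifnot(is(cloneSummary, "SpectrumSummary"))
  if (is(controlSummaries, "SpectrumSummary"))
    controlSummaries <- list(controlSummaries)
  if (!length(controlSummaries))
    stop("need at least one control summary", call. = FALSE)
  ctrl <- vapply(controlSummaries, function(s) s@counts,
                 numeric(length(MUTATION_CLASSES)))
  ctrlMean <- rowMeans(ctrl)
  fc <- ifelse(ctrlMean > 0, cloneSummary@counts / ctrlMean, NA_real_)
  data.frame(cloneId = cloneSummary@cloneId, class = MUTATION_CLASSES,
             cloneCount = unname(cloneSummary@counts),
             controlMean = unname(ctrlMean), foldChange = unname(fc),
             flagged = unname(ctrlMean == 0), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write / read a per-clone spectrum table
#'
#' One row per clone with columns \code{clone}, \code{total}, the six
#' substitution classes and \code{indel}; tab-delimited. The pair
#' round-trips: reading a written table reproduces the input summaries.
#'
#' @param summaries List of [SpectrumSummary-class] objects with distinct
#'   clone ids.
#' @param path Output path (for the writer); input path (for the reader).
#' @return \code{reportSpectrumTable}: invisibly, the data.frame written.
#'   \code{readSpectrumTable}: a named list of [SpectrumSummary-class].
#' @export
reportSpectrumTable <- function(summaries, path = NULL) {
  if (is(summaries, "SpectrumSummary")) summaries <- list(summaries)
  ids <- vapply(summaries, function(s) s@cloneId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate clone id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- t(vapply(summaries, function(s) s@counts,
                numeric(length(MUTATION_CLASSES))))
  df <- data.frame(clone = ids,
                   total = vapply(summaries, function(s) s@total, numeric(1)),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname reportSpectrumTable
#' @export
readSpectrumTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("clone", "total", MUTATION_CLASSES)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("spectrum table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    spectrumSummary(df$clone[i],
                    setNames(as.numeric(df[i, MUTATION_CLASSES]),
                             MUTATION_CLASSES)))
  names(out) <- df$clone
  out
}
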