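#' Inter-clone mutation overlap matrix
#'
#' Counts mutations shared between every pair of clone catalogs. In the
#' default allele-aware mode a shared mutation is an identical
#' (chrom, pos, ref, alt); in position-only mode, an identical (chrom, pos),
#' exposing the looser "same location" reading. The diagonal holds each
#' catalog's size.
#'
#' @param catalogs List of two or more [VariantCatalog-class] objects with
#'   distinct clone ids.
#' @param matchMode \code{"allele_aware"} (default) or
#'   \code{"position_only"}.
#' @return A symmetric integer matrix with clone ids as dimnames.
#' @export
#' @examples
#' a <- VariantCatalog("a", "chr1", c(1L, 5L), c("C", "G"), c("T", "A"))
#' b <- VariantCatalog("b", "chr1", c(5L, 9L), c("G", "A"), c("A", "T"))
#' overlapMatrix(list(a, b))
overlapMatrix <- function(catalogs,
                          matchMode = c("allele_aware", "position_only")) {
  matchMode <- match.arg(matchMode)
  if (length(catalogs) < 2L) stop("need at least two catalogs", call. = FALSE)
  ids <- vapply(catalogs, cloneId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate clone id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  keys <- lapply(catalogs, function(cat) {
    v <- variants(cat)
    if (matchMode == "allele_aware")
      unique(paste(v$chrom, v$pos, v$ref, v$alt))
    else unique(paste(v$chrom, v$pos))
  })
  k <- length(catalogs)
  m <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    m[i, i] <- length(catalogs[[i]])
    for (j in seq_len(k)) {
      if (j <= i) next
      ov <- length(intersect(keys[[i]], keys[[j]]))
      m[i, j] <- ov
      m[j, i] <- ov
    }
  }
  m
}

#' Per-chromosome distribution of C:G mutations with group statistics
#'
#' For each clone whose total catalog size exceeds \code{minTotal}, computes
#' the fraction of its mutations in the stated classes falling on each
#' chromosome; then, for each named group of clones, the per-chromosome mean
#' and standard deviation (sample formula, n - 1) across the group's clones.
#' Groups of size one get \code{NA} SD and are flagged.
#'
#' @param catalogs List of [VariantCatalog-class] objects.
#' @param grouping Optional named list mapping group name to clone ids.
#' @param classes Substitution classes counted; default \code{c("C:G>T:A",
#'   "C:G>G:C")}.
#' @param minTotal Clones with total variants \code{<= minTotal} are
#'   excluded (default 500); exclusions are reported.
#' @param chromosomes Chromosome set for the output; defaults to all
#'   chromosomes seen across the eligible catalogs (pass
#'   \code{chromNames(genome)} to fix the full set).
#' @return List with \code{perClone} (data.frame clone x chromosome
#'   fractions, long format), \code{groups} (data.frame with group,
#'   chromosome, mean, sd, n, flagged) and \code{excluded} (character vector
#'   of excluded clone ids).
#' @export
chromosomeDistribution <- function(catalogs, grouping = NULL,
                                   classes = c("C:G>T:A", "C:G>G:C"),
                                   minTotal = 500L, chromosomes = NULL) {
  ids <- vapply(catalogs, cloneId, character(1))
  names(catalogs) <- ids
  sizes <- vapply(catalogs, length, integer(1))
  eligible <- sizes > minTotal
  excluded <- ids[!eligible]
  catalogs <- catalogs[eligible]
  if (!length(catalogs))
    stop("no clone exceeds minTotal = ", minTotal, call. = FALSE)
  perClone <- lapply(catalogs, function(cat) {
    v <- variants(cat)
    v <- v[v$kind == "SNV", , drop = FALSE]
    if (nrow(v)) {
      cls <- classifySubstitution(v$ref, v$alt)
      v <- v[cls %in% classes, , drop = FALSE]
    }
    if (!nrow(v))
      stop("clone ", cloneId(cat), " has no mutations in the stated classes",
           call. = FALSE)
    table(v$chrom)
  })
  if (is.null(chromosomes))
    chromosomes <- sort(unique(unlist(lapply(perClone, names))))
  fracMat <- do.call(rbind, lapply(perClone, function(tb) {
    x <- setNames(numeric(length(chromosomes)), chromosomes)
    x[names(tb)] <- as.numeric(tb)
    x / sum(x)
  }))
  long <- data.frame(clone = rep(rownames(fracMat), each = ncol(fracMat)),
                     chrom = rep(chromosomes, times = nrow(fracMat)),
                     fraction = as.vector(t(fracMat)),
                     stringsAsFactors = FALSE)
  groups <- NULL
  if (!is.null(grouping)) {
    rows <- list()
    for (g in names(grouping)) {
      members <- intersect(grouping[[g]], rownames(fracMat))
      if (!length(members))
        stop("group '", g, "' is empty after the minTotal filter",
             call. = FALSE)
      sub <- fracMat[members, , drop = FALSE]
      rows[[g]] <- data.frame(group = g, chrom = chromosomes,
                              mean = colMeans(sub),
                              sd = if (nrow(sub) >= 2L) apply(sub, 2L, stats::sd)
                                   else NA_real_,
                              n = nrow(sub), flagged = nrow(sub) < 2L,
                              stringsAsFactors = FALSE, row.names = NULL)
    }
    groups <- do.call(rbind, rows)
    rownames(groups) <- NULL
  }
  list(perClone = long, groups = groups, excluded = excluded)
}
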