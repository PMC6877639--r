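#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString readBStringSet readDNAStringSet
#'   reverseComplement alphabetFrequency oligonucleotideFrequency writeXStringSet
#'   consensusMatrix matchPattern
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges Views
#' @importFrom stats phyper rbinom rpois runif setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

## The seven pyrimidine-normalised mutation classes, in reporting order.
MUTATION_CLASSES <- c("C:G>T:A", "C:G>G:C", "C:G>A:T",
                      "A:T>C:G", "A:T>G:C", "A:T>T:A", "indel")

SUBSTITUTION_CLASSES <- MUTATION_CLASSES[1:6]

#' Reference genome container
#'
#' Holds a set of named chromosome sequences over the alphabet A/C/G/T/N,
#' always stored uppercase. Soft-masked (lowercase) stretches present in the
#' source FASTA are retained as an optional per-chromosome mask track of
#' \link[IRanges]{IRanges}, but play no role in any analysis here.
#'
#' @slot seqs A named \link[Biostrings]{DNAStringSet}; names are chromosome
#'   names and must be unique.
#' @slot mask A named list of \link[IRanges]{IRanges} giving soft-masked
#'   intervals (1-based) per chromosome; may be empty.
#' @seealso [readGenomeFasta()], [chromNames()], [chromLengths()]
#' @export
setClass("Genome", slots = c(seqs = "DNAStringSet", mask = "list"))

setValidity("Genome", function(object) {
  nm <- names(object@seqs)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    return("all chromosomes must be named")
  if (anyDuplicated(nm))
    return(paste0("duplicate chromosome name(s): ",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  af <- alphabetFrequency(object@seqs, baseOnly = TRUE)
  # baseOnly 'other' column counts everything outside A/C/G/T; N is allowed
  nN <- vapply(seq_along(object@seqs), function(i)
    sum(alphabetFrequency(object@seqs[[i]])[["N"]]), numeric(1))
  if (any(af[, "other"] > nN))
    return("sequences may contain only A/C/G/T/N")
  TRUE
})

#' One clone's catalog of called variants
#'
#' An ordered, duplicate-free collection of variants (SNV, insertion,
#' deletion or multi-base substitution) called in a single clone against the
#' parental line. Positions are 0-based internally (the first reference base
#' of the allele); standard file formats keep their native conventions on
#' read/write. Indels are VCF-anchored: the first reference base is shared
#' between ref and alt.
#'
#' @slot cloneId Single character label for the clone.
#' @slot variants A data.frame with columns \code{chrom}, \code{pos}
#'   (0-based integer), \code{ref}, \code{alt}, \code{kind}
#'   (\code{"SNV"}, \code{"insertion"}, \code{"deletion"} or \code{"MNV"}),
#'   sorted by (chrom, pos, ref, alt).
#' @slot provenance Free-text origin note.
#' @seealso [VariantCatalog()], [readVariantVcf()], [summarizeCatalog()]
#' @export
setClass("VariantCatalog",
         slots = c(cloneId = "character", variants = "data.frame",
                   provenance = "character"))

setValidity("VariantCatalog", function(object) {
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "kind")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns", paste(need, collapse = ", ")))
  if (length(object@cloneId) != 1L) return("cloneId must be a single string")
  if (nrow(v) == 0L) return(TRUE)
  if (any(v$pos < 0L)) return("positions must be >= 0")
  if (!all(grepl("^[ACGT]+$", v$ref)) || !all(grepl("^[ACGT]+$", v$alt)))
    return("alleles must contain only A/C/G/T")
  key <- paste(v$chrom, v$pos, v$ref, v$alt)
  if (anyDuplicated(key)) return("duplicate (chrom,pos,ref,alt) entries")
  o <- order(v$chrom, v$pos, v$ref, v$alt, method = "radix")
  if (!identical(o, seq_len(nrow(v)))) return("variants must be sorted")
  snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$ref != v$alt
  if (!all(snv == (v$kind == "SNV")))
    return("kind must be SNV exactly when ref and alt are distinct single bases")
  TRUE
})

#' Somatic filter thresholds
#'
#' The four cut-offs applied after the paired Fisher exact test, all strict
#' inequalities: p-value below \code{maxP}, parental ("normal") VAF below
#' \code{maxNormalVaf}, clone ("tumor") VAF above \code{minTumorVaf}, and
#' clone alt-supporting reads above \code{minTumorAltReads}.
#'
#' The default \code{minTumorVaf} is the exact fraction 1/3; the printed
#' constant 0.3333 is available by passing it explicitly (the two differ
#' only for sites whose VAF falls in (0.3333, 1/3]).
#'
#' @seealso [filterThresholds()], [filterSomatic()]
#' @export
setClass("FilterThresholds",
         slots = c(maxP = "numeric", maxNormalVaf = "numeric",
                   minTumorVaf = "numeric", minTumorAltReads = "numeric"))

setValidity("FilterThresholds", function(object) {
  if (object@maxP <= 0 || object@maxP > 1) return("maxP must be in (0, 1]")
  if (object@maxNormalVaf < 0 || object@maxNormalVaf >= object@minTumorVaf ||
      object@minTumorVaf > 1)
    return("need 0 <= maxNormalVaf < minTumorVaf <= 1")
  if (object@minTumorAltReads < 0) return("minTumorAltReads must be >= 0")
  TRUE
})

#' Mutation-spectrum summary for one clone
#'
#' Counts of the six pyrimidine-normalised substitution classes plus indels,
#' and their total; one summary corresponds to one row of a per-clone
#' spectrum table.
#'
#' @slot cloneId Clone label.
#' @slot counts Named numeric vector over the seven classes
#'   (see \code{mutationClasses()}).
#' @slot total Sum of the seven counts.
#' @seealso [summarizeCatalog()], [typeFraction()], [foldChanges()]
#' @export
setClass("SpectrumSummary",
         slots = c(cloneId = "character", counts = "numeric", total = "numeric"))

setValidity("SpectrumSummary", function(object) {
  if (!identical(names(object@counts), MUTATION_CLASSES))
    return("counts must be named by the seven mutation classes")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (!isTRUE(all.equal(sum(object@counts), object@total)))
    return("total must equal the sum of class counts")
  TRUE
})

#' Flanking-context window around a mutated cytosine
#'
#' Number of positions kept upstream (5' of the mutated base on its oriented
#' strand) and downstream (3'). The default asymmetric -5..+25 window matches
#' the range over which base-editor deamination footprints are usually
#' displayed.
#'
#' @seealso [contextWindow()], [extractContexts()]
#' @export
setClass("ContextWindow", slots = c(upstream = "integer", downstream = "integer"))

setValidity("ContextWindow", function(object) {
  if (object@upstream < 1L || object@downstream < 1L)
    return("upstream and downstream must both be >= 1")
  TRUE
})

#' Strand-oriented context sequences for a set of mutated cytosines
#'
#' Fixed-width windows around mutated C:G sites, re-oriented so the mutated
#' base always reads C at the centre. Windows running off a chromosome end or
#' overlapping an N are excluded (never padded) and tallied by reason.
#'
#' @slot contexts \link[Biostrings]{DNAStringSet} of equal-width oriented
#'   windows; position \code{upstream + 1} of every sequence is C.
#' @slot upstream,downstream Window geometry (integers).
#' @slot excluded Named integer vector of exclusion counts
#'   (\code{out_of_bounds}, \code{contains_n}).
#' @seealso [extractContexts()], [buildContextMatrix()], [tcwFraction()]
#' @export
setClass("OrientedContextSet",
         slots = c(contexts = "DNAStringSet", upstream = "integer",
                   downstream = "integer", excluded = "integer"))

setValidity("OrientedContextSet", function(object) {
  w <- object@upstream + 1L + object@downstream
  if (length(object@contexts) &&
      !all(Biostrings::width(object@contexts) == w))
    return("all contexts must have width upstream + 1 + downstream")
  if (length(object@contexts)) {
    ctr <- as.character(Biostrings::subseq(object@contexts,
                                           object@upstream + 1L,
                                           object@upstream + 1L))
    if (!all(ctr == "C")) return("centre base must read C in every context")
  }
  TRUE
})

#' Position frequency matrix with information content
#'
#' Column-wise base frequencies and per-position information content
#' (2 - H bits, H the Shannon entropy of the column) over a set of
#' equal-width oriented contexts; the sequence-logo statistics.
#'
#' @slot positions Integer positions relative to the mutated C (position 0).
#' @slot freq 4 x L matrix of relative frequencies, rows A/C/G/T.
#' @slot infoBits Numeric vector of per-position information content in bits.
#' @slot n Number of contexts the matrix was built from.
#' @seealso [buildContextMatrix()], [writeContextMatrix()]
#' @export
setClass("ContextMatrix",
         slots = c(positions = "integer", freq = "matrix",
                   infoBits = "numeric", n = "integer"))

setValidity("ContextMatrix", function(object) {
  if (!identical(rownames(object@freq), c("A", "C", "G", "T")))
    return("freq must have rows A, C, G, T")
  if (ncol(object@freq) != length(object@positions))
    return("freq must have one column per position")
  cs <- colSums(object@freq)
  if (any(abs(cs - 1) > 1e-9)) return("column frequencies must sum to 1")
  if (any(object@infoBits < -1e-12 | object@infoBits > 2 + 1e-12))
    return("information content must lie in [0, 2] bits")
  TRUE
})

#' Simulation parameters for synthetic study inputs
#'
#' Describes one synthetic "study": an i.i.d. random genome, per-clone
#' mutation catalogs made of a uniform background component, an APOBEC
#' component planted at TCW cytosines (C->T with probability
#' \code{apobecCtFraction}, else C->G), and short indels; plus paired
#' clone/parental read counts at every planted site with clonal heterozygous
#' variants (expected allele fraction \code{expectedVaf}) at
#' \code{meanDepth} coverage.
#'
#' @seealso [simulationConfig()], [generateGenome()], [plantMutations()],
#'   [simulateCounts()]
#' @export
setClass("SimulationConfig",
         slots = c(genomeLength = "numeric", gcContent = "numeric",
                   nChromosomes = "integer", nBackgroundMutations = "integer",
                   nApobecMutations = "integer", apobecCtFraction = "numeric",
                   nIndels = "integer", cloneCount = "integer",
                   expectedVaf = "numeric", meanDepth = "numeric",
                   errorRate = "numeric", nDecoys = "integer",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
  cnt <- c(object@nBackgroundMutations, object@nApobecMutations,
           object@nIndels, object@cloneCount, object@nDecoys)
  if (any(cnt < 0L)) return("all counts must be >= 0")
  fr <- c(object@gcContent, object@apobecCtFraction, object@expectedVaf,
          object@errorRate)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@genomeLength < 1000) return("genomeLength must be >= 1000")
  if (object@nChromosomes < 1L) return("need at least one chromosome")
  if (object@meanDepth <= 0) return("meanDepth must be > 0")
  TRUE
})

#' @describeIn Genome-class Number of chromosomes.
#' @param x,object A \code{Genome}.
#' @export
setMethod("length", "Genome", function(x) length(x@seqs))

setMethod("show", "Genome", function(object) {
  cat("Genome with", length(object@seqs), "chromosome(s),",
      sum(as.numeric(Biostrings::width(object@seqs))), "bp total\n")
  nm <- names(object@seqs)
  k <- min(5L, length(nm))
  for (i in seq_len(k))
    cat("  ", nm[i], ": ", Biostrings::width(object@seqs)[i], " bp\n", sep = "")
  if (length(nm) > k) cat("  ...\n")
})

#' @describeIn VariantCatalog-class Number of variants in the catalog.
#' @param x,object A \code{VariantCatalog}.
#' @export
setMethod("length", "VariantCatalog", function(x) nrow(x@variants))

setMethod("show", "VariantCatalog", function(object) {
  v <- object@variants
  cat("VariantCatalog '", object@cloneId, "': ", nrow(v), " variant(s)",
      sep = "")
  if (nrow(v)) {
    tb <- table(factor(v$kind, levels = c("SNV", "insertion", "deletion", "MNV")))
    cat(" (", paste(paste0(tb, " ", names(tb)), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "SpectrumSummary", function(object) {
  cat("SpectrumSummary '", object@cloneId, "': total ", object@total, "\n",
      sep = "")
  print(object@counts)
})

setMethod("show", "ContextMatrix", function(object) {
  cat("ContextMatrix over positions ", min(object@positions), "..",
      max(object@positions), " (n = ", object@n, " contexts)\n", sep = "")
  cat("  information content at position 0: ",
      round(object@infoBits[match(0L, object@positions)], 3), " bits\n",
      sep = "")
})

setMethod("show", "OrientedContextSet", function(object) {
  cat("OrientedContextSet: ", length(object@contexts), " context(s), window -",
      object@upstream, "..+", object@downstream, "\n", sep = "")
  if (sum(object@excluded))
    cat("  excluded:", paste(names(object@excluded), object@excluded,
                             collapse = ", "), "\n")
})
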