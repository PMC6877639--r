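#' Accessors for core classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x A \code{Genome}, \code{VariantCatalog}, \code{SpectrumSummary},
#'   \code{OrientedContextSet} or \code{ContextMatrix}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname accessors
#' @export
setMethod("chromNames", "Genome", function(x) names(x@seqs))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setMethod("chromLengths", "Genome", function(x)
  setNames(Biostrings::width(x@seqs), names(x@seqs)))

#' @rdname accessors
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))

#' @rdname accessors
#' @export
setMethod("genomeSeqs", "Genome", function(x) x@seqs)

#' @rdname accessors
#' @export
setGeneric("softMask", function(x) standardGeneric("softMask"))

#' @rdname accessors
#' @export
setMethod("softMask", "Genome", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("cloneId", function(x) standardGeneric("cloneId"))

#' @rdname accessors
#' @export
setMethod("cloneId", "VariantCatalog", function(x) x@cloneId)

#' @rdname accessors
#' @export
setMethod("cloneId", "SpectrumSummary", function(x) x@cloneId)

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setMethod("variants", "VariantCatalog", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setMethod("classCounts", "SpectrumSummary", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("totalVariants", function(x) standardGeneric("totalVariants"))

#' @rdname accessors
#' @export
setMethod("totalVariants", "SpectrumSummary", function(x) x@total)

#' @rdname accessors
#' @export
setGeneric("contexts", function(x) standardGeneric("contexts"))

#' @rdname accessors
#' @export
setMethod("contexts", "OrientedContextSet", function(x) x@contexts)

#' @rdname accessors
#' @export
setGeneric("excludedCounts", function(x) standardGeneric("excludedCounts"))

#' @rdname accessors
#' @export
setMethod("excludedCounts", "OrientedContextSet", function(x) x@excluded)

#' @rdname accessors
#' @export
setGeneric("infoBits", function(x) standardGeneric("infoBits"))

#' @rdname accessors
#' @export
setMethod("infoBits", "ContextMatrix", function(x)
  setNames(x@infoBits, x@positions))

#' @rdname accessors
#' @export
setGeneric("baseFreq", function(x) standardGeneric("baseFreq"))

#' @rdname accessors
#' @export
setMethod("baseFreq", "ContextMatrix", function(x) {
  m <- x@freq
  colnames(m) <- x@positions
  m
})

#' The seven mutation classes
#'
#' Reporting order of the pyrimidine-normalised substitution classes plus
#' the indel class.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' mutationClasses()
mutationClasses <- function() MUTATION_CLASSES
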