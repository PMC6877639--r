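#' Construct a simulation configuration
#'
#' Defaults emulate the measurement conditions of a high-mutation-load
#' base-edited clone characterised by ~40x whole-genome sequencing: clonal
#' heterozygous variants (expected allele fraction 0.5), a mutation catalog
#' dominated by an APOBEC component at TCW cytosines that is mostly C->T
#' with a minority of C->G, a small uniform background over the six
#' substitution classes, and a handful of short indels. The genome itself
#' is i.i.d. with human-like GC content.
#'
#' @param genomeLength Total genome size in bp (>= 1000). Default 1e6.
#' @param gcContent Fraction of G+C. Default 0.41.
#' @param nChromosomes Number of equal-length chromosomes. Default 4.
#' @param nBackgroundMutations Uniform background SNVs per clone. Default 100.
#' @param nApobecMutations APOBEC-component SNVs per clone, planted at TCW
#'   cytosines. Default 900.
#' @param apobecCtFraction Probability an APOBEC event is C->T (else C->G).
#'   Default 0.85.
#' @param nIndels 1-3 bp insertions/deletions per clone. Default 40.
#' @param cloneCount Number of clones. Default 1.
#' @param expectedVaf Expected clone allele fraction. Default 0.5.
#' @param meanDepth Mean sequencing depth (Poisson). Default 40.
#' @param errorRate Per-read error rate feeding spurious alt reads.
#'   Default 0.001.
#' @param nDecoys Non-mutant decoy sites added to each clone's count table.
#'   Default 200.
#' @param seed Integer seed; all randomness in the simulator derives from
#'   it. Default 1.
#' @return A [SimulationConfig-class].
#' @export
#' @examples
#' simulationConfig(seed = 42)
simulationConfig <- function(genomeLength = 1e6, gcContent = 0.41,
                             nChromosomes = 4L, nBackgroundMutations = 100L,
                             nApobecMutations = 900L, apobecCtFraction = 0.85,
                             nIndels = 40L, cloneCount = 1L,
                             expectedVaf = 0.5, meanDepth = 40,
                             errorRate = 0.001, nDecoys = 200L, seed = 1L) {
  new("SimulationConfig", genomeLength = genomeLength, gcContent = gcContent,
      nChromosomes = as.integer(nChromosomes),
      nBackgroundMutations = as.integer(nBackgroundMutations),
      nApobecMutations = as.integer(nApobecMutations),
      apobecCtFraction = apobecCtFraction, nIndels = as.integer(nIndels),
      cloneCount = as.integer(cloneCount), expectedVaf = expectedVaf,
      meanDepth = meanDepth, errorRate = errorRate,
      nDecoys = as.integer(nDecoys), seed = as.integer(seed))
}

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2; the total length is split evenly across chromosomes named
#' \code{chr1..chrK}. Reproducible under the config seed.
#'
#' @param config A [SimulationConfig-class].
#' @return A [Genome-class].
#' @export
#' @examples
#' g <- generateGenome(simulationConfig(genomeLength = 2000, seed = 7))
#' chromLengths(g)
generateGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(.subSeed(config@seed, 1L))
  gc <- config@gcContent
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  k <- config@nChromosomes
  lens <- rep(floor(config@genomeLength / k), k)
  lens[k] <- lens[k] + config@genomeLength - sum(lens)
  seqs <- vapply(lens, function(L)
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(k))
  Genome(seqs)
}

## inventory of TCW-context cytosines on both strands:
## plus strand  TC[AT] -> C at match start + 1
## minus strand [AT]GA -> G at match start + 1 (oriented strand is minus)
.tcwSites <- function(genome) {
  out <- list()
  for (ch in chromNames(genome)) {
    s <- .chromSeq(genome, ch)
    plus <- sort(c(Biostrings::start(matchPattern("TCA", s)),
                   Biostrings::start(matchPattern("TCT", s))))
    minus <- sort(c(Biostrings::start(matchPattern("TGA", s)),
                    Biostrings::start(matchPattern("AGA", s))))
    out[[ch]] <- rbind(
      if (length(plus)) data.frame(chrom = ch, pos = plus, strand = "+",
                                   stringsAsFactors = FALSE),
      if (length(minus)) data.frame(chrom = ch, pos = minus, strand = "-",
                                    stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Plant synthetic mutation catalogs with a known APOBEC component
#'
#' Builds \code{cloneCount} catalogs on the given genome. Background SNVs
#' fall uniformly over genome positions, with the alternate base drawn
#' uniformly among the three non-reference bases (so the six substitution
#' classes are hit uniformly conditional on the reference base). APOBEC
#' SNVs are placed at TCW-context cytosines on either strand: C->T with
#' probability \code{apobecCtFraction}, else C->G (on the oriented strand;
#' minus-strand events appear as G->A / G->C in reference coordinates).
#' Indels are 1-3 bp VCF-anchored insertions or deletions at random
#' positions. All positions within a clone are drawn without replacement.
#'
#' @param genome A [Genome-class].
#' @param config A [SimulationConfig-class]. The genome must contain at
#'   least \code{nApobecMutations} TCW sites.
#' @return List with \code{catalogs} (list of [VariantCatalog-class], one
#'   per clone, ids \code{simclone1..K}) and \code{truth} (data.frame with
#'   cloneId, chrom, pos, ref, alt, origin in
#'   \{background, apobec, indel\}, and the trinucleotide context at
#'   planting, oriented so APOBEC events read TCW).
#' @export
plantMutations <- function(genome, config) {
  stopifnot(is(genome, "Genome"), is(config, "SimulationConfig"))
  set.seed(.subSeed(config@seed, 2L))
  tcw <- .tcwSites(genome)
  nTcw <- if (is.null(tcw)) 0L else nrow(tcw)
  if (nTcw < config@nApobecMutations)
    stop(sprintf("genome has only %d TCW sites; %d needed", nTcw,
                 config@nApobecMutations), call. = FALSE)
  lens <- chromLengths(genome)
  chars <- lapply(genomeSeqs(genome), as.character)
  baseAt <- function(ch, pos0) substr(chars[[ch]], pos0 + 1L, pos0 + 1L)
  triAt <- function(ch, pos0) substr(chars[[ch]], pos0, pos0 + 2L)

  catalogs <- list(); truthAll <- list()
  for (cl in seq_len(config@cloneCount)) {
    used <- new.env(hash = TRUE)
    take <- function(ch, pos0) {  # claim a position; FALSE if taken
      k <- paste0(ch, ":", pos0)
      if (!is.null(used[[k]])) return(FALSE)
      used[[k]] <- TRUE
      TRUE
    }
    rec <- list()
    ## APOBEC component at TCW cytosines
    if (config@nApobecMutations > 0L) {
      pick <- tcw[sample.int(nTcw, config@nApobecMutations), , drop = FALSE]
      isCT <- runif(nrow(pick)) < config@apobecCtFraction
      for (i in seq_len(nrow(pick))) {
        ch <- pick$chrom[i]; p0 <- pick$pos[i]
        if (!take(ch, p0)) next
        plus <- pick$strand[i] == "+"
        ref <- if (plus) "C" else "G"
        alt <- if (isCT[i]) (if (plus) "T" else "A")
               else (if (plus) "G" else "C")
        tri <- triAt(ch, p0)
        if (!plus) tri <- .revcompChar(tri)
        rec[[length(rec) + 1L]] <- data.frame(
          chrom = ch, pos = p0, ref = ref, alt = alt, origin = "apobec",
          context = tri, stringsAsFactors = FALSE)
      }
    }
    ## uniform background SNVs
    nBg <- config@nBackgroundMutations
    guard <- 0L
    while (nBg > 0L && guard < 50L) {
      guard <- guard + 1L
      ch <- sample(names(lens), nBg, replace = TRUE,
                   prob = lens / sum(lens))
      p0 <- as.integer(floor(runif(nBg) * lens[ch]))
      for (i in seq_len(nBg)) {
        ref <- baseAt(ch[i], p0[i])
        if (ref == "N" || !take(ch[i], p0[i])) next
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        tri <- if (p0[i] >= 1L && p0[i] + 1L < lens[ch[i]])
          triAt(ch[i], p0[i]) else NA_character_
        if (!is.na(tri) && ref %in% c("G"))
          tri <- .revcompChar(tri)
        rec[[length(rec) + 1L]] <- data.frame(
          chrom = ch[i], pos = p0[i], ref = ref, alt = alt,
          origin = "background", context = tri, stringsAsFactors = FALSE)
        nBg <- nBg - 1L
      }
    }
    ## short indels, VCF-anchored
    nInd <- config@nIndels
    guard <- 0L
    while (nInd > 0L && guard < 50L) {
      guard <- guard + 1L
      ch <- sample(names(lens), nInd, replace = TRUE,
                   prob = lens / sum(lens))
      p0 <- as.integer(floor(runif(nInd) * (lens[ch] - 4L)))
      for (i in seq_len(nInd)) {
        ln <- sample.int(3L, 1L)
        anchor <- baseAt(ch[i], p0[i])
        if (anchor == "N" || !take(ch[i], p0[i])) next
        if (runif(1) < 0.5) {  # insertion
          ins <- paste(sample(c("A", "C", "G", "T"), ln, replace = TRUE),
                       collapse = "")
          ref <- anchor; alt <- paste0(anchor, ins)
        } else {               # deletion
          span <- substr(chars[[ch[i]]], p0[i] + 1L, p0[i] + 1L + ln)
          if (grepl("N", span, fixed = TRUE)) next
          ref <- span; alt <- anchor
        }
        rec[[length(rec) + 1L]] <- data.frame(
          chrom = ch[i], pos = p0[i], ref = ref, alt = alt,
          origin = "indel", context = NA_character_,
          stringsAsFactors = FALSE)
        nInd <- nInd - 1L
      }
    }
    truth <- do.call(rbind, rec)
    truth$cloneId <- paste0("simclone", cl)
    cat <- VariantCatalog(paste0("simclone", cl),
                          chrom = truth$chrom, pos = truth$pos,
                          ref = truth$ref, alt = truth$alt, genome = genome,
                          provenance = sprintf("simulated (seed %d)",
                                               config@seed))
    catalogs[[cl]] <- cat
    truthAll[[cl]] <- truth
  }
  truth <- do.call(rbind, truthAll)
  rownames(truth) <- NULL
  list(catalogs = catalogs, truth = truth[c("cloneId", "chrom", "pos", "ref",
                                            "alt", "origin", "context")])
}

#' Simulate paired clone/parental read counts
#'
#' At every catalog site, the clone ("tumor") depth is Poisson with mean
#' \code{meanDepth} (zero depths redrawn to 1) and alt reads are binomial
#' with success probability \code{expectedVaf} adjusted by the error rate
#' (\code{vaf (1 - e) + (1 - vaf) e}); parental ("normal") alt reads are
#' binomial at the bare error rate. \code{nDecoys} additional non-mutant
#' sites carry error-only alt reads in both samples.
#'
#' @param genome A [Genome-class].
#' @param catalog A [VariantCatalog-class] of planted variants.
#' @param config A [SimulationConfig-class].
#' @param seed Optional seed override; defaults to a value derived from the
#'   config seed.
#' @return Data.frame of paired counts (columns as [readCountsTable()]) with
#'   an extra \code{siteClass} column in \{planted, decoy\}.
#' @export
simulateCounts <- function(genome, catalog, config, seed = NULL) {
  stopifnot(is(genome, "Genome"), is(catalog, "VariantCatalog"),
            is(config, "SimulationConfig"))
  set.seed(if (is.null(seed)) .subSeed(config@seed, 3L) else seed)
  v <- variants(catalog)
  lens <- chromLengths(genome)
  chars <- lapply(genomeSeqs(genome), as.character)
  nP <- nrow(v); nD <- config@nDecoys
  ## decoy sites: random non-mutant positions with a random alt allele
  dChrom <- character(0); dPos <- integer(0); dRef <- character(0)
  dAlt <- character(0)
  usedKeys <- paste0(v$chrom, ":", v$pos)
  guard <- 0L
  while (length(dPos) < nD && guard < 50L) {
    guard <- guard + 1L
    need <- nD - length(dPos)
    ch <- sample(names(lens), need, replace = TRUE, prob = lens / sum(lens))
    p0 <- as.integer(floor(runif(need) * lens[ch]))
    for (i in seq_len(need)) {
      k <- paste0(ch[i], ":", p0[i])
      if (k %in% usedKeys) next
      ref <- substr(chars[[ch[i]]], p0[i] + 1L, p0[i] + 1L)
      if (ref == "N") next
      usedKeys <- c(usedKeys, k)
      dChrom <- c(dChrom, ch[i]); dPos <- c(dPos, p0[i])
      dRef <- c(dRef, ref)
      dAlt <- c(dAlt, sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
    }
  }
  chrom <- c(v$chrom, dChrom)
  pos <- c(v$pos, dPos)
  ref <- c(v$ref, dRef)
  alt <- c(v$alt, dAlt)
  siteClass <- c(rep("planted", nP), rep("decoy", length(dPos)))
  n <- length(pos)
  e <- config@errorRate
  pAlt <- config@expectedVaf * (1 - e) + (1 - config@expectedVaf) * e
  tDepth <- rpois(n, config@meanDepth); tDepth[tDepth == 0L] <- 1L
  nDepth <- rpois(n, config@meanDepth); nDepth[nDepth == 0L] <- 1L
  pT <- ifelse(siteClass == "planted", pAlt, e)
  tAlt <- rbinom(n, tDepth, pT)
  nAlt <- rbinom(n, nDepth, e)
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    tRef = tDepth - tAlt, tAlt = tAlt,
                    nRef = nDepth - nAlt, nAlt = nAlt,
                    siteClass = siteClass, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full simulator
#'
#' Convenience wrapper: genome, catalogs with truth records, and per-clone
#' paired counts, all from one config.
#'
#' @param config A [SimulationConfig-class].
#' @return List with \code{genome}, \code{catalogs}, \code{truth} and
#'   \code{counts} (named list of per-clone count data.frames).
#' @export
#' @examples
#' sim <- simulateStudy(simulationConfig(genomeLength = 50000,
#'                                       nApobecMutations = 50L,
#'                                       nBackgroundMutations = 10L,
#'                                       nIndels = 5L, nDecoys = 20L))
#' length(sim$catalogs[[1]])
simulateStudy <- function(config = simulationConfig()) {
  genome <- generateGenome(config)
  planted <- plantMutations(genome, config)
  counts <- lapply(seq_along(planted$catalogs), function(i)
    simulateCounts(genome, planted$catalogs[[i]], config,
                   seed = .subSeed(config@seed, 3L + i)))
  names(counts) <- vapply(planted$catalogs, cloneId, character(1))
  list(genome = genome, catalogs = planted$catalogs, truth = planted$truth,
       counts = counts)
}

#' Write a simulation bundle to disk
#'
#' Writes the genome FASTA, one truth VCF and one allele-count TSV per
#' clone, the truth table, and a JSON manifest of all simulation
#' parameters.
#'
#' @param sim Result of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @param config The [SimulationConfig-class] used (recorded in the
#'   manifest).
#' @return Invisibly, a character vector of the files written.
#' @export
writeSimulationBundle <- function(sim, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  fa <- file.path(dir, "genome.fa")
  writeGenomeFasta(sim$genome, fa); files <- c(files, fa)
  for (i in seq_along(sim$catalogs)) {
    id <- cloneId(sim$catalogs[[i]])
    vcf <- file.path(dir, paste0(id, ".truth.vcf"))
    writeVariantVcf(sim$catalogs[[i]], vcf, genome = sim$genome)
    tsv <- file.path(dir, paste0(id, ".counts.tsv"))
    writeCountsTable(sim$counts[[id]], tsv)
    files <- c(files, vcf, tsv)
  }
  tt <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, tt)
  manifest <- file.path(dir, "manifest.json")
  cfg <- sapply(slotNames(config), function(s) slot(config, s),
                simplify = FALSE)
  jsonlite::write_json(list(parameters = cfg, files = basename(files)),
                       manifest, auto_unbox = TRUE, digits = NA)
  files <- c(files, manifest)
  invisible(files)
}
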