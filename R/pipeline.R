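#' Read and validate an analysis configuration
#'
#' The configuration is a flat YAML file. Recognised keys (all optional
#' unless a stage needs them):
#' \describe{
#'   \item{genome}{Path to the reference FASTA.}
#'   \item{counts}{Named map clone id -> paired allele-count TSV (runs the
#'     somatic filter stage).}
#'   \item{vcfs}{Named map clone id -> VCF of called variants (used when
#'     the filter stage is skipped).}
#'   \item{offtargets}{Path to the predicted off-target site TSV.}
#'   \item{out_dir}{Output directory.}
#'   \item{thresholds}{Map with max_p, max_normal_vaf, min_tumor_vaf,
#'     min_tumor_alt_reads.}
#'   \item{window}{Map with upstream, downstream (context window).}
#'   \item{pam}{Map with offset_start, offset_end.}
#'   \item{background}{Map with n_samples for the PAM background.}
#'   \item{controls}{Clone ids used as the fold-change control set.}
#'   \item{grouping}{Named map group name -> clone ids (chromosome
#'     distribution error bars).}
#'   \item{cg_logo_min}{Minimum C:G>G:C count for that class's context
#'     matrix (default 40).}
#'   \item{chrom_min_total}{Minimum catalog size for the chromosome
#'     distribution (default 500).}
#'   \item{stages}{Subset of filter, spectrum, signature, pamscan,
#'     offtarget, compare; default all runnable.}
#'   \item{seed}{Integer seed for the sampled PAM background.}
#' }
#'
#' @param path Path to the YAML config.
#' @return A validated named list with class \code{"cbescanConfig"}.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  cfg$genome <- resolve(cfg$genome)
  cfg$offtargets <- resolve(cfg$offtargets)
  for (k in c("counts", "vcfs"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- lapply(cfg[[k]], resolve)
  .validateConfig(cfg)
  class(cfg) <- "cbescanConfig"
  cfg
}

.validateConfig <- function(cfg) {
  if (is.null(cfg$genome))
    stop("config error: 'genome' is required", call. = FALSE)
  paths <- c(cfg$genome, cfg$offtargets,
             unlist(cfg$counts), unlist(cfg$vcfs))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config error: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(cfg$counts) && is.null(cfg$vcfs))
    stop("config error: need 'counts' or 'vcfs'", call. = FALSE)
  th <- cfg$thresholds
  if (!is.null(th))
    filterThresholds(th$max_p %||% 0.001, th$max_normal_vaf %||% 0.05,
                     th$min_tumor_vaf %||% (1 / 3),
                     th$min_tumor_alt_reads %||% 6)  # validity check
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full off-target analysis pipeline
#'
#' Executes, in order and as applicable: somatic filtering of paired count
#' tables (or direct VCF loading), per-clone spectrum summaries and fold
#' changes versus the control clones, context-signature extraction with TCW
#' statistics, PAM proximity scanning with a sampled genomic background,
#' off-target intersection, and inter-clone comparisons. All outputs are
#' TSV/FASTA/JSON files under \code{out_dir}, plus a \code{manifest.json}
#' recording the seed, package version, input checksums and exclusion
#' counts, so reported denominators are auditable.
#'
#' @param config A config list from [readAnalysisConfig()], or a path to a
#'   YAML config file.
#' @param outDir Output directory; overrides the config's \code{out_dir}.
#' @return Invisibly, a list with the in-memory results of every stage run.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readAnalysisConfig(config)
  outDir <- outDir %||% config$out_dir %||% stop("no output directory given")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  allStages <- c("filter", "spectrum", "signature", "pamscan", "offtarget",
                 "compare")
  stages <- config$stages %||% allStages
  res <- list()
  runLog <- list(exclusions = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  genome <- stage("load", readGenomeFasta(config$genome))

  ## --- variant catalogs: filter stage or direct VCFs ---
  if ("filter" %in% stages && !is.null(config$counts)) {
    th <- config$thresholds
    thr <- filterThresholds(th$max_p %||% 0.001,
                            th$max_normal_vaf %||% 0.05,
                            th$min_tumor_vaf %||% (1 / 3),
                            th$min_tumor_alt_reads %||% 6)
    res$filter <- stage("filter", {
      lapply(names(config$counts), function(id) {
        sites <- readCountsTable(config$counts[[id]])
        fs <- filterSomatic(sites, thr, cloneId = id, genome = genome)
        writeFilterAudit(fs$calls,
                         file.path(outDir, paste0(id, ".audit.tsv")))
        writeVariantVcf(fs$catalog,
                        file.path(outDir, paste0(id, ".somatic.vcf")),
                        genome = genome)
        fs
      })
    })
    catalogs <- lapply(res$filter, `[[`, "catalog")
  } else if (!is.null(config$vcfs)) {
    catalogs <- stage("load", lapply(names(config$vcfs), function(id)
      readVariantVcf(config$vcfs[[id]], genome = genome, cloneId = id)))
  } else stop("stage 'filter': no counts or vcfs available", call. = FALSE)
  names(catalogs) <- vapply(catalogs, cloneId, character(1))
  res$catalogs <- catalogs

  ## --- mutation spectrum ---
  if ("spectrum" %in% stages) {
    res$spectrum <- stage("spectrum", {
      summaries <- lapply(catalogs, summarizeCatalog)
      reportSpectrumTable(summaries, file.path(outDir, "spectrum.tsv"))
      fc <- NULL
      ctrl <- intersect(config$controls %||% character(0), names(summaries))
      if (length(ctrl)) {
        fc <- do.call(rbind, lapply(
          summaries[setdiff(names(summaries), ctrl)],
          foldChanges, controlSummaries = summaries[ctrl]))
        write.table(fc, file.path(outDir, "fold_changes.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      list(summaries = summaries, foldChanges = fc)
    })
  }

  ## --- context signature ---
  if ("signature" %in% stages) {
    win <- contextWindow(config$window$upstream %||% 5L,
                         config$window$downstream %||% 25L)
    cgMin <- config$cg_logo_min %||% 40L
    res$signature <- stage("signature", {
      lapply(names(catalogs), function(id) {
        cat <- catalogs[[id]]
        out <- list()
        for (cls in c("C:G>T:A", "C:G>G:C")) {
          tag <- if (cls == "C:G>T:A") "ct" else "cg"
          sm <- summarizeCatalog(cat)
          if (cls == "C:G>G:C" && classCounts(sm)[[cls]] <= cgMin) next
          octx <- extractContexts(cat, genome, window = win, classes = cls)
          if (!length(contexts(octx))) next
          writeContextsFasta(octx, file.path(outDir,
                                             paste0(id, ".", tag,
                                                    ".contexts.fa")))
          cm <- buildContextMatrix(octx)
          writeContextMatrix(cm, file.path(outDir,
                                           paste0(id, ".", tag,
                                                  ".context_matrix.tsv")))
          out[[tag]] <- list(contexts = octx, matrix = cm)
          runLog$exclusions[[paste(id, tag, sep = ".")]] <<-
            as.list(excludedCounts(octx))
        }
        out$tcw <- tcwEnrichment(cat, genome, window = win)
        jsonlite::write_json(out$tcw,
                             file.path(outDir, paste0(id, ".tcw.json")),
                             auto_unbox = TRUE, digits = NA)
        out
      })
    })
    names(res$signature) <- names(catalogs)
  }

  ## --- PAM proximity ---
  if ("pamscan" %in% stages) {
    res$pamscan <- stage("pamscan", {
      prox <- lapply(catalogs, pamProximityFraction, genome = genome,
                     offsetStart = config$pam$offset_start %||% 15L,
                     offsetEnd = config$pam$offset_end %||% 20L)
      bg <- backgroundPamFrequency(genome,
                                   nSamples = config$background$n_samples %||% 1e6,
                                   seed = config$seed %||% 1L)
      jsonlite::write_json(list(perClone = prox, background = bg),
                           file.path(outDir, "pam.json"),
                           auto_unbox = TRUE, digits = NA)
      list(perClone = prox, background = bg)
    })
  }

  ## --- off-target intersection ---
  if ("offtarget" %in% stages && !is.null(config$offtargets)) {
    res$offtarget <- stage("offtarget", {
      sites <- readOffTargetSites(config$offtargets)
      lapply(names(catalogs), function(id) {
        hit <- intersectOffTargets(catalogs[[id]], sites)
        write.table(hit$perSite,
                    file.path(outDir, paste0(id, ".offtarget_hits.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        hit
      })
    })
    names(res$offtarget) <- names(catalogs)
  }

  ## --- comparative ---
  if ("compare" %in% stages && length(catalogs) >= 2L) {
    res$compare <- stage("compare", {
      om <- overlapMatrix(catalogs)
      write.table(om, file.path(outDir, "overlap_matrix.tsv"), sep = "\t",
                  quote = FALSE, col.names = NA)
      cd <- tryCatch(
        chromosomeDistribution(catalogs, grouping = config$grouping,
                               minTotal = config$chrom_min_total %||% 500L,
                               chromosomes = chromNames(genome)),
        error = function(e) NULL)
      if (!is.null(cd)) {
        write.table(cd$perClone, file.path(outDir, "chrom_distribution.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        runLog$exclusions$chrom_distribution <- as.list(
          setNames(rep("below minTotal", length(cd$excluded)), cd$excluded))
      }
      list(overlap = om, chromDistribution = cd)
    })
  }

  ## --- manifest ---
  inputs <- c(genome = config$genome, offtargets = config$offtargets,
              unlist(config$counts), unlist(config$vcfs))
  sums <- tools::md5sum(unname(inputs))
  names(sums) <- names(inputs)
  manifest <- list(
    package = as.character(packageVersion("cbescan")),
    seed = config$seed %||% 1L,
    stages = stages,
    inputs = as.list(sums),
    exclusions = runLog$exclusions)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
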