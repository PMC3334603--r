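#' Pipeline configuration
#'
#' Exactly one of \code{synthetic} (a [syntheticConfig()], in which case the
#' pipeline generates its own data) or \code{inputs} (a named list of file
#' paths: \code{genomeFasta}, \code{genesBed}, \code{classTsv},
#' \code{alusPath}, \code{aluDialect}, \code{signalsBed}, \code{signalsTsv},
#' \code{consensusFasta}) must be supplied.
#'
#' @param synthetic a [syntheticConfig()] or \code{NULL}.
#' @param inputs named list of input paths or \code{NULL}.
#' @param sites aligned site set the scanning PWM is built from (default:
#'   the configured planted motif when running synthetically).
#' @param pseudocount,background PWM construction parameters.
#' @param threshold scan score threshold in bits (default 8.7).
#' @param strands strands to scan (default \code{"both"}).
#' @param upstreamLen upstream window (default 5000).
#' @param alignMatch,alignMismatch,gapOpen,gapExtend local-alignment scores.
#' @param proximityThreshold antisense proximity rule in bases
#'   (default 5000).
#' @param alpha detection p-value cutoff for antisense signals
#'   (default 0.05).
#' @param binWidth proximity histogram bin width (default 500).
#' @param outputDir optional directory for stage TSVs and the run manifest.
#' @param seed global seed recorded in the manifest (the synthetic seed
#'   governs generation).
#' @return configuration list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(synthetic = NULL, inputs = NULL, sites = NULL,
                           pseudocount = 0.25, background = rep(0.25, 4),
                           threshold = 8.7, strands = "both",
                           upstreamLen = 5000L,
                           alignMatch = 2, alignMismatch = -3,
                           gapOpen = 8, gapExtend = 1,
                           proximityThreshold = 5000L, alpha = 0.05,
                           binWidth = 500L, outputDir = NULL, seed = 1L) {
  if (is.null(synthetic) == is.null(inputs))
    .stopf("exactly one of 'synthetic' and 'inputs' must be supplied")
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Summarise orientation bias from an orientation count table
#'
#' Per row and in aggregate: the site load of each orientation, i.e.
#' 100 x (HSF sites in Alus of that orientation) / (Alus of that
#' orientation), and the antisense/sense fold ratio of the per-Alu site
#' rates (\code{NA} when the sense rate is 0).
#'
#' @param table data.frame with columns \code{n_sense_alus},
#'   \code{n_antisense_alus}, \code{n_hits_in_sense_alus},
#'   \code{n_hits_in_antisense_alus} (as from [tabulateOrientation()] or
#'   [readOrientationCounts()]).
#' @return list with \code{perRow} (the input plus \code{sense_percent},
#'   \code{antisense_percent}, \code{fold}) and \code{aggregate} (one-row
#'   data.frame of the pooled percents and fold).
#' @export
summarizeOrientationBias <- function(table) {
  if (!NROW(table)) .stopf("orientation table is empty")
  pr <- function(h, a) ifelse(a > 0, 100 * h / a, NA_real_)
  perRow <- table
  perRow$sense_percent <- pr(table$n_hits_in_sense_alus, table$n_sense_alus)
  perRow$antisense_percent <-
    pr(table$n_hits_in_antisense_alus, table$n_antisense_alus)
  perRow$fold <- perRow$antisense_percent / perRow$sense_percent
  perRow$fold[!is.finite(perRow$fold)] <- NA_real_
  agg <- data.frame(
    sense_percent = pr(sum(table$n_hits_in_sense_alus),
                       sum(table$n_sense_alus)),
    antisense_percent = pr(sum(table$n_hits_in_antisense_alus),
                           sum(table$n_antisense_alus)))
  agg$fold <- agg$antisense_percent / agg$sense_percent
  list(perRow = perRow, aggregate = agg)
}

#' Read an orientation count table TSV
#'
#' @param path TSV with header columns \code{expression_class},
#'   \code{region_kind}, \code{n_sense_alus}, \code{n_antisense_alus},
#'   \code{n_hits_in_sense_alus}, \code{n_hits_in_antisense_alus}.
#' @return data.frame.
#' @export
readOrientationCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("n_sense_alus", "n_antisense_alus", "n_hits_in_sense_alus",
            "n_hits_in_antisense_alus")
  if (!all(need %in% names(df)))
    .stopf("orientation count table must have columns: %s",
           paste(need, collapse = ", "))
  df
}

#' Run the full Alu/HSF analysis pipeline
#'
#' Executes scan, Alu/non-Alu and orientation classification, density
#' statistics, consensus positional mapping and antisense proximity
#' analysis, either on a self-generated synthetic dataset or on user files.
#' With \code{outputDir} set, stage TSVs and a run manifest (seed,
#' parameters, input checksums) are written after all stages complete, so a
#' failing stage leaves no partial output behind.
#'
#' @param config a [pipelineConfig()].
#' @return list with the pipeline stage results: \code{dataset} (synthetic
#'   runs only), \code{pwm}, \code{regions}, \code{classified},
#'   \code{categories}, \code{orientationTable}, \code{biasSummary},
#'   \code{densities}, \code{comparisons}, \code{mappings},
#'   \code{positional}, \code{proximityRecords}, \code{proximitySummary},
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pipelineConfig")) .stopf("need a pipelineConfig")
  checksums <- character(0)
  if (!is.null(config$synthetic)) {
    dataset <- generateDataset(config$synthetic)
    genome <- datasetGenome(dataset)
    genes <- datasetGenes(dataset)
    rawAlus <- datasetAlus(dataset)
    mcols(rawAlus) <- mcols(rawAlus)[, c("alu_id", "subfamily")]
    signals <- datasetSignals(dataset)
    consensus <- datasetConsensus(dataset)
    sites <- if (is.null(config$sites)) config$synthetic$motif
             else config$sites
  } else {
    ins <- config$inputs
    need <- c("genomeFasta", "genesBed", "alusPath")
    for (nm in need)
      if (is.null(ins[[nm]])) .stopf("input '%s' is required", nm)
    paths <- unlist(ins[vapply(ins, is.character, TRUE)])
    paths <- paths[!names(paths) %in% "aluDialect"]
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      .stopf("input file not found: %s", missing[[1]])
    checksums <- md5sum(paths)
    dataset <- NULL
    genome <- readDNAStringSet(ins$genomeFasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    genes <- loadGeneModels(ins$genesBed, ins$classTsv)
    seqlengths(genes) <- width(genome)[match(seqlevels(genes),
                                             names(genome))]
    rawAlus <- loadAlus(ins$alusPath,
                        dialect = if (is.null(ins$aluDialect))
                          "repeatmasker_out" else ins$aluDialect)
    signals <- if (!is.null(ins$signalsBed))
      loadSignals(ins$signalsBed, ins$signalsTsv) else GRanges()
    consensus <- if (!is.null(ins$consensusFasta))
      readDNAStringSet(ins$consensusFasta) else NULL
    sites <- config$sites
    if (is.null(sites)) .stopf("'sites' must be supplied for file inputs")
  }

  pwm <- buildPWM(sites, pseudocount = config$pseudocount,
                  background = config$background)
  regions <- extractRegions(genes, upstreamLen = config$upstreamLen)
  hostAlus <- assignAluHosts(rawAlus, regions)

  ## scan each region and classify its hits against the host gene's Alus
  classified <- list()
  for (i in seq_along(regions)) {
    reg <- regions[i]
    contig <- as.character(seqnames(reg))
    seqStr <- as.character(subseq(genome[[contig]], start(reg), end(reg)))
    hits <- scanRegion(pwm, seqStr, threshold = config$threshold,
                       strands = config$strands,
                       region_id = paste(mcols(reg)$gene_id,
                                         mcols(reg)$kind, sep = "|"))
    geneAlus <- hostAlus[mcols(hostAlus)$host_gene == mcols(reg)$gene_id]
    classified[[i]] <- assignHitsToAlus(hits, geneAlus, reg)
  }
  classified <- do.call(rbind, classified)

  geneKinds <- unique(data.frame(
    gene_id = mcols(regions)$gene_id, region_kind = mcols(regions)$kind,
    stringsAsFactors = FALSE))
  categories <- do.call(rbind, lapply(seq_len(nrow(geneKinds)), function(i)
    categorizeGene(classified, geneKinds$gene_id[i],
                   geneKinds$region_kind[i])))

  orientationTable <- tabulateOrientation(classified, hostAlus, genes)
  biasSummary <- summarizeOrientationBias(orientationTable)

  densities <- rbind(
    aluDensityTable(hostAlus, regions),
    hsfDensityTable(classified, regions, "hsf_density_total"),
    hsfDensityTable(classified, regions, "hsf_density_alu"),
    hsfDensityTable(classified, regions, "hsf_density_nonalu"))
  clsOf <- stats::setNames(mcols(genes)$expression_class,
                           mcols(genes)$gene_id)
  comparisons <- .densityComparisons(densities, clsOf)

  ## positional mapping of in-Alu hits onto subfamily consensus coordinates
  mappings <- NULL
  if (!is.null(consensus)) {
    inAlu <- classified[classified$in_alu, , drop = FALSE]
    aluIdx <- match(inAlu$alu_id, mcols(hostAlus)$alu_id)
    cache <- list()
    maps <- vector("list", nrow(inAlu))
    for (i in seq_len(nrow(inAlu))) {
      alu <- hostAlus[aluIdx[i]]
      aid <- mcols(alu)$alu_id
      if (is.null(cache[[aid]])) {
        contig <- as.character(seqnames(alu))
        aluSeq <- as.character(subseq(genome[[contig]], start(alu),
                                      end(alu)))
        if (as.character(strand(alu)) == "-") aluSeq <- .revcomp(aluSeq)
        subfam <- mcols(alu)$subfamily
        if (!subfam %in% names(consensus)) next
        cache[[aid]] <- localAlign(
          aluSeq, as.character(consensus[[subfam]]),
          match = config$alignMatch, mismatch = config$alignMismatch,
          gapOpen = config$gapOpen, gapExtend = config$gapExtend,
          query_id = aid, subject_id = subfam)
      }
      maps[[i]] <- mapHitToConsensus(inAlu[i, ], alu, cache[[aid]])
    }
    maps <- maps[!vapply(maps, is.null, TRUE)]
    mappings <- if (length(maps)) do.call(rbind, maps) else NULL
  }
  ## a preferred position must carry a meaningful share of the mappings:
  ## rare threshold-crossings in diverged copies otherwise register as
  ## single-count "modes"
  positional <- positionHistogram(
    mappings, minCount = max(2L, ceiling(0.05 * NROW(mappings))))

  ## antisense proximity in genic regions of signal-bearing genes
  detected <- filterDetected(signals, alpha = config$alpha)
  proximityRecords <- NULL
  if (length(detected)) {
    strandOf <- stats::setNames(as.character(strand(genes)),
                                mcols(genes)$gene_id)
    recs <- vector("list", length(detected))
    for (i in seq_along(detected)) {
      sig <- list(signal_id = mcols(detected)$signal_id[i],
                  gene_id = mcols(detected)$gene_id[i],
                  start = start(detected)[i] - 1L, end = end(detected)[i])
      sites_i <- classified[classified$gene_id == sig$gene_id &
                              classified$region_kind == "genic" &
                              classified$in_alu &
                              !is.na(classified$alu_orientation) &
                              classified$alu_orientation == "antisense", ,
                            drop = FALSE]
      recs[[i]] <- nearestSite(sig, sites_i, strandOf[[sig$gene_id]],
                               threshold = config$proximityThreshold)
    }
    recs <- recs[!vapply(recs, is.null, TRUE)]
    proximityRecords <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  proxSummary <- proximitySummary(proximityRecords,
                                  binWidth = config$binWidth,
                                  threshold = config$proximityThreshold)

  manifest <- data.frame(
    key = c("seed", "threshold", "pseudocount", "upstream_len",
            "proximity_threshold", "alpha", "strands",
            if (length(checksums)) paste0("md5_", names(checksums))),
    value = c(config$seed, config$threshold, config$pseudocount,
              config$upstreamLen, config$proximityThreshold, config$alpha,
              config$strands, unname(checksums)),
    stringsAsFactors = FALSE)

  result <- list(dataset = dataset, pwm = pwm, regions = regions,
                 classified = classified, categories = categories,
                 orientationTable = orientationTable,
                 biasSummary = biasSummary, densities = densities,
                 comparisons = comparisons, mappings = mappings,
                 positional = positional,
                 proximityRecords = proximityRecords,
                 proximitySummary = proxSummary, manifest = manifest)

  if (!is.null(config$outputDir)) .writeReport(result, config$outputDir)
  result
}

## Table-1-analogue Welch comparisons for every metric and region kind
.densityComparisons <- function(densities, clsOf) {
  pairs <- list(c("up", "random"), c("down", "random"), c("down", "up"))
  rows <- list()
  densities$class <- clsOf[densities$gene_id]
  for (metric in unique(densities$metric))
    for (k in c("upstream5kb", "genic"))
      for (p in pairs) {
        a <- densities$value[densities$metric == metric &
                               densities$region_kind == k &
                               densities$class == p[1]]
        b <- densities$value[densities$metric == metric &
                               densities$region_kind == k &
                               densities$class == p[2]]
        if (length(a) < 2L || length(b) < 2L) next
        if (stats::var(a) == 0 && stats::var(b) == 0) next
        cmp <- compareGroups(a, b, p[1], p[2])
        cmp$metric <- metric
        cmp$region_kind <- k
        rows[[length(rows) + 1L]] <- cmp
      }
  if (length(rows)) do.call(rbind, rows) else NULL
}

## stage TSVs + manifest written only after all stages succeeded; staged
## through a temporary directory so a crash leaves no partial output
.writeReport <- function(result, outputDir) {
  tmp <- file.path(tempfile("aluhsf_report_"))
  dir.create(tmp, recursive = TRUE)
  wt <- function(x, f) if (!is.null(x) && NROW(x))
    write.table(x, file.path(tmp, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  writeHits(result$classified, tsvPath = file.path(tmp, "classified_hits.tsv"))
  wt(result$categories, "gene_categories.tsv")
  wt(result$orientationTable, "orientation_counts.tsv")
  wt(result$biasSummary$perRow, "orientation_bias.tsv")
  wt(result$densities, "densities.tsv")
  wt(result$comparisons, "density_comparisons.tsv")
  wt(result$mappings, "consensus_mappings.tsv")
  wt(result$positional$histogram, "position_histogram.tsv")
  wt(result$proximityRecords, "proximity_records.tsv")
  wt(result$manifest, "manifest.tsv")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(tmp))
    file.copy(file.path(tmp, f), file.path(outputDir, f), overwrite = TRUE)
  unlink(tmp, recursive = TRUE)
  invisible(outputDir)
}
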