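#' Write a synthetic dataset to disk in standard formats
#'
#' Emits: genome FASTA; genes as single-block BED12 plus a gene/class TSV;
#' Alus as both RepeatMasker-style .out (1-based inclusive) and BED6
#' (0-based half-open, name = subfamily); antisense signals as BED6 with a
#' sidecar TSV carrying detection p-values; the truth table TSV; and the
#' subfamily consensus FASTA.
#'
#' @param dataset a [SyntheticAluDataset-class].
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the written paths.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(genome = file.path(dir, "genome.fa"),
         genes_bed = file.path(dir, "genes.bed"),
         classes = file.path(dir, "gene_classes.tsv"),
         alus_out = file.path(dir, "alus.out"),
         alus_bed = file.path(dir, "alus.bed"),
         signals_bed = file.path(dir, "antisense_signals.bed"),
         signals_tsv = file.path(dir, "antisense_signals.tsv"),
         truth = file.path(dir, "truth.tsv"),
         consensus = file.path(dir, "consensus.fa"))
  writeXStringSet(datasetGenome(dataset), p["genome"])
  writeGeneModels(datasetGenes(dataset), p["genes_bed"], p["classes"])
  writeAlus(datasetAlus(dataset), p["alus_out"], "repeatmasker_out")
  writeAlus(datasetAlus(dataset), p["alus_bed"], "bed6")
  sig <- datasetSignals(dataset)
  bed <- data.frame(chrom = as.character(seqnames(sig)),
                    start = start(sig) - 1L, end = end(sig),
                    name = if (length(sig)) mcols(sig)$signal_id else character(0),
                    score = 0L, strand = as.character(strand(sig)))
  write.table(bed, p["signals_bed"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  sidecar <- data.frame(signal_id = if (length(sig)) mcols(sig)$signal_id else character(0),
                        gene_id = if (length(sig)) mcols(sig)$gene_id else character(0),
                        detection_p = if (length(sig)) mcols(sig)$detection_p else numeric(0))
  write.table(sidecar, p["signals_tsv"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(datasetTruth(dataset), p["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeXStringSet(datasetConsensus(dataset), p["consensus"])
  invisible(p)
}

#' Load antisense probe signals from BED6 plus a detection-p sidecar TSV
#'
#' @param bedPath BED6 of probe intervals (name = signal id).
#' @param tsvPath sidecar TSV with columns \code{signal_id},
#'   \code{gene_id}, \code{detection_p}.
#' @return \code{GRanges} with \code{signal_id}, \code{gene_id},
#'   \code{detection_p} metadata.
#' @export
loadSignals <- function(bedPath, tsvPath) {
  gr <- tryCatch(rtracklayer::import(bedPath, format = "BED"),
                 error = function(e)
                   .stopf("cannot parse BED file %s: %s", bedPath,
                          conditionMessage(e)))
  sc <- read.delim(tsvPath, stringsAsFactors = FALSE)
  m <- match(mcols(gr)$name, sc$signal_id)
  if (anyNA(m)) .stopf("signal id missing from sidecar TSV: %s",
                       mcols(gr)$name[which(is.na(m))[1]])
  out <- gr
  mcols(out) <- NULL
  mcols(out)$signal_id <- sc$signal_id[m]
  mcols(out)$gene_id <- sc$gene_id[m]
  mcols(out)$detection_p <- sc$detection_p[m]
  out
}
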