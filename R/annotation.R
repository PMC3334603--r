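#' Load gene models with expression classes
#'
#' Reads one-interval-per-gene models from BED12 (via \pkg{rtracklayer}) or
#' a refFlat-style TSV, removes records on \code{chr*_random} / \code{chr*_hap}
#' chromosomes (genomic-location-ambiguous assemblies), and attaches
#' expression classes from a two-column \code{gene_id <TAB> class} table
#' (genes absent from the table default to \code{unchanged}).
#'
#' @param path BED12 or refFlat file.
#' @param classTable optional path to the gene_id/class TSV (no header).
#' @param format \code{"auto"} (by extension), \code{"bed12"} or
#'   \code{"refflat"}.
#' @return \code{GRanges} of transcript intervals with \code{gene_id} and
#'   \code{expression_class} metadata.
#' @export
loadGeneModels <- function(path, classTable = NULL,
                           format = c("auto", "bed12", "refflat")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("gene model file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12"
              else "refflat"
  if (format == "bed12") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                     .stopf("cannot parse BED file %s: %s", path,
                            conditionMessage(e)))
    ids <- mcols(gr)$name
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    rows <- vector("list", length(fields))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 6L)
        .stopf("%s line %d: expected >= 6 refFlat fields, got %d",
               path, i, length(f))
      txs <- suppressWarnings(as.integer(f[5])); txe <- suppressWarnings(as.integer(f[6]))
      if (is.na(txs) || is.na(txe) || txs >= txe || !(f[4] %in% c("+", "-")))
        .stopf("%s line %d: malformed refFlat record", path, i)
      rows[[i]] <- data.frame(name = f[2], chrom = f[3], strand = f[4],
                              start0 = txs, end0 = txe,
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    gr <- GRanges(df$chrom, IRanges(df$start0 + 1L, df$end0),
                  strand = df$strand)
    ids <- df$name
  }
  if (anyDuplicated(ids))
    .stopf("duplicate gene_id in %s: %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep <- !grepl("_random$", as.character(seqnames(gr))) &
          !grepl("_hap", as.character(seqnames(gr)))
  gr <- gr[keep]
  ids <- ids[keep]
  mcols(gr) <- NULL
  mcols(gr)$gene_id <- ids
  cls <- rep("unchanged", length(gr))
  if (!is.null(classTable)) {
    ct <- read.delim(classTable, header = FALSE,
                     col.names = c("gene_id", "class"),
                     stringsAsFactors = FALSE)
    m <- match(ids, ct$gene_id)
    cls[!is.na(m)] <- ct$class[m[!is.na(m)]]
  }
  mcols(gr)$expression_class <- cls
  gr
}

#' Write gene models as single-block BED12 plus a class sidecar TSV
#'
#' @param genes gene \code{GRanges} (as from [loadGeneModels()] or
#'   [datasetGenes()]).
#' @param bedPath BED12 output path.
#' @param classPath optional gene_id/class TSV output path.
#' @return invisible \code{NULL}.
#' @export
writeGeneModels <- function(genes, bedPath, classPath = NULL) {
  s0 <- start(genes) - 1L
  e0 <- end(genes)
  df <- data.frame(chrom = as.character(seqnames(genes)), start = s0,
                   end = e0, name = mcols(genes)$gene_id, score = 0L,
                   strand = as.character(strand(genes)), thickStart = s0,
                   thickEnd = e0, rgb = "0", blockCount = 1L,
                   blockSizes = paste0(e0 - s0, ","), blockStarts = "0,")
  write.table(df, bedPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(classPath))
    write.table(data.frame(mcols(genes)$gene_id,
                           mcols(genes)$expression_class),
                classPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Derive upstream-5kb and genic analysis regions
#'
#' For a plus-strand gene the upstream window is the \code{upstreamLen}
#' bases before the transcript start; for a minus-strand gene, the bases
#' after the transcript end. Windows are truncated at contig boundaries
#' (contig lengths are taken from \code{seqlengths(genes)}). The genic
#' region is the transcript interval itself.
#'
#' @param genes gene \code{GRanges} with \code{gene_id} metadata and
#'   seqlengths set.
#' @param upstreamLen upstream window length (default 5000).
#' @return \code{GRanges} with \code{gene_id} and \code{kind}
#'   (\code{upstream5kb} / \code{genic}) metadata; strand is the host
#'   gene's strand.
#' @export
extractRegions <- function(genes, upstreamLen = 5000L) {
  lens <- seqlengths(genes)[as.character(seqnames(genes))]
  if (anyNA(lens)) .stopf("seqlengths(genes) must be set for all contigs")
  plus <- as.character(strand(genes)) == "+"
  upS <- ifelse(plus, pmax(1L, start(genes) - upstreamLen), end(genes) + 1L)
  upE <- ifelse(plus, start(genes) - 1L,
                pmin(lens, end(genes) + upstreamLen))
  keepUp <- upE >= upS
  up <- GRanges(seqnames(genes)[keepUp],
                IRanges(upS[keepUp], upE[keepUp]),
                strand = strand(genes)[keepUp],
                seqlengths = seqlengths(genes))
  mcols(up)$gene_id <- mcols(genes)$gene_id[keepUp]
  mcols(up)$kind <- "upstream5kb"
  genic <- genes
  mcols(genic) <- NULL
  mcols(genic)$gene_id <- mcols(genes)$gene_id
  mcols(genic)$kind <- "genic"
  out <- c(up, genic)
  out[order(mcols(out)$gene_id, mcols(out)$kind)]
}

#' Load Alu annotations from RepeatMasker .out or BED6
#'
#' RepeatMasker coordinates are 1-based inclusive and are kept as such in
#' the returned \code{GRanges} (the Bioconductor convention); the
#' RepeatMasker \code{C} orientation maps to strand \code{-}. Only records
#' whose repeat name begins with \code{Alu} (plus \code{FLAM}/\code{FRAM}
#' when \code{includeFlam = TRUE}) are retained.
#'
#' @param path annotation file.
#' @param dialect \code{"repeatmasker_out"} or \code{"bed6"}.
#' @param includeFlam also keep FLAM/FRAM records (default \code{FALSE}).
#' @return \code{GRanges} with \code{alu_id} and \code{subfamily} metadata.
#' @export
loadAlus <- function(path, dialect = c("repeatmasker_out", "bed6"),
                     includeFlam = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("Alu annotation file not found: %s", path)
  if (dialect == "repeatmasker_out") {
    lines <- readLines(path)
    isData <- grepl("^\\s*[0-9]", lines)
    rows <- vector("list", sum(isData))
    k <- 0L
    for (i in which(isData)) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 11L)
        .stopf("%s line %d: expected >= 11 RepeatMasker fields", path, i)
      b <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
      if (is.na(b) || is.na(e) || b > e)
        .stopf("%s line %d: malformed coordinates", path, i)
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = f[5], start = b, end = e,
                              strand = if (f[9] == "C") "-" else "+",
                              subfamily = f[10], stringsAsFactors = FALSE)
    }
    df <- if (k) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), subfamily = character(0))
  } else {
    gr0 <- tryCatch(rtracklayer::import(path, format = "BED"),
                    error = function(e)
                      .stopf("cannot parse BED file %s: %s", path,
                             conditionMessage(e)))
    df <- data.frame(chrom = as.character(seqnames(gr0)),
                     start = start(gr0), end = end(gr0),
                     strand = as.character(strand(gr0)),
                     subfamily = mcols(gr0)$name, stringsAsFactors = FALSE)
  }
  fams <- "^Alu"
  if (includeFlam) fams <- "^(Alu|FLAM|FRAM)"
  df <- df[grepl(fams, df$subfamily), , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$alu_id <- sprintf("alu%05d", seq_len(nrow(df)))
  mcols(gr)$subfamily <- df$subfamily
  gr
}

#' Write Alu annotations in RepeatMasker .out or BED6 dialect
#'
#' BED6 is written 0-based half-open with the subfamily as the name column;
#' RepeatMasker .out is written 1-based inclusive with \code{C} for minus
#' strand and placeholder alignment statistics.
#'
#' @param alus Alu \code{GRanges} with \code{subfamily} metadata.
#' @param path output path.
#' @param dialect \code{"repeatmasker_out"} or \code{"bed6"}.
#' @return invisible \code{NULL}.
#' @export
writeAlus <- function(alus, path, dialect = c("repeatmasker_out", "bed6")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed6") {
    df <- data.frame(chrom = as.character(seqnames(alus)),
                     start = start(alus) - 1L, end = end(alus),
                     name = mcols(alus)$subfamily, score = 0L,
                     strand = as.character(strand(alus)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
      "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
      ""), con)
    st <- as.character(strand(alus))
    for (i in seq_along(alus)) {
      writeLines(sprintf(
        "  225  10.0  0.0  0.0  %s %8d %8d (0) %s %-14s SINE/Alu %8d %6d (0) %5d",
        as.character(seqnames(alus))[i], start(alus)[i], end(alus)[i],
        if (st[i] == "-") "C" else "+", mcols(alus)$subfamily[i],
        1L, width(alus)[i], i), con)
    }
  }
  invisible(NULL)
}

#' Classify an Alu's orientation relative to its host transcript
#'
#' Sense when the Alu strand matches the host gene strand, antisense
#' otherwise. Vectorised over both arguments.
#'
#' @param aluStrand,geneStrand character vectors of \code{"+"} / \code{"-"}.
#' @return character vector of \code{"sense"} / \code{"antisense"}.
#' @export
assignAluOrientation <- function(aluStrand, geneStrand) {
  aluStrand <- as.character(aluStrand)
  geneStrand <- as.character(geneStrand)
  if (any(!aluStrand %in% c("+", "-")) || any(!geneStrand %in% c("+", "-")))
    .stopf("orientation requires defined +/- strands on both records")
  ifelse(aluStrand == geneStrand, "sense", "antisense")
}

#' Assign Alus to host-gene analysis regions by the midpoint rule
#'
#' An Alu belongs to every gene region that contains its midpoint, so an Alu
#' straddling the upstream/genic boundary gets a single deterministic region
#' label per gene, while an Alu inside two genes' regions is duplicated with
#' distinct hosts (per-transcript counting frame).
#'
#' @param alus Alu \code{GRanges} (needs \code{alu_id}, \code{subfamily}).
#' @param regions region \code{GRanges} from [extractRegions()].
#' @return \code{GRanges} of host-assigned Alus with \code{host_gene},
#'   \code{region_kind} and \code{orientation_class} metadata (one row per
#'   Alu-gene assignment).
#' @export
assignAluHosts <- function(alus, regions) {
  if (!length(alus)) {
    out <- alus
    mcols(out)$host_gene <- character(0)
    mcols(out)$region_kind <- character(0)
    mcols(out)$orientation_class <- character(0)
    return(out)
  }
  mid <- start(alus) + width(alus) %/% 2L
  midGr <- GRanges(seqnames(alus), IRanges(mid, mid))
  ov <- findOverlaps(midGr, regions, ignore.strand = TRUE)
  out <- alus[queryHits(ov)]
  keep <- c("alu_id", "subfamily")
  mcols(out) <- mcols(out)[, keep, drop = FALSE]
  mcols(out)$host_gene <- mcols(regions)$gene_id[subjectHits(ov)]
  mcols(out)$region_kind <- mcols(regions)$kind[subjectHits(ov)]
  mcols(out)$orientation_class <- assignAluOrientation(
    as.character(strand(out)),
    as.character(strand(regions))[subjectHits(ov)])
  out
}
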