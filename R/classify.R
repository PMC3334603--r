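#' Classify motif hits as Alu / non-Alu within one gene region
#'
#' Hits are lifted from region-relative to genomic (contig) coordinates and
#' labelled by the midpoint rule: a hit is in an Alu iff the hit's midpoint
#' base lies inside the Alu interval. When overlapping Alus both contain the
#' midpoint, the Alu with the larger overlap with the hit wins; ties go to
#' the smaller start coordinate.
#'
#' @param hits data.frame from [scanRegion()] (region-relative 0-based
#'   coordinates).
#' @param alus host-assigned Alu \code{GRanges} for the same gene (needs
#'   \code{alu_id}, \code{orientation_class}).
#' @param region single-row region \code{GRanges} from [extractRegions()]
#'   the hits were scanned in.
#' @return data.frame of classified hits with genomic 0-based half-open
#'   \code{start}/\code{end}, \code{gene_id}, \code{region_kind},
#'   \code{in_alu}, \code{alu_id}, \code{alu_orientation}.
#' @export
assignHitsToAlus <- function(hits, alus, region) {
  if (length(region) != 1L) .stopf("region must be a single range")
  regStart0 <- start(region) - 1L
  regLen <- width(region)
  out <- data.frame(
    gene_id = rep(mcols(region)$gene_id, nrow(hits)),
    region_kind = rep(mcols(region)$kind, nrow(hits)),
    chrom = rep(as.character(seqnames(region)), nrow(hits)),
    start = regStart0 + hits$start, end = regStart0 + hits$end,
    strand = hits$strand, score = hits$score,
    matched_word = hits$matched_word,
    in_alu = logical(nrow(hits)),
    alu_id = rep(NA_character_, nrow(hits)),
    alu_orientation = rep(NA_character_, nrow(hits)),
    stringsAsFactors = FALSE)
  if (!nrow(hits)) return(out)
  if (any(hits$start < 0L) || any(hits$end > regLen))
    .stopf("hit outside the scanned region: coordinate frame mismatch")
  if (!length(alus)) return(out)
  aS0 <- start(alus) - 1L
  aE0 <- end(alus)
  for (i in seq_len(nrow(hits))) {
    mid0 <- out$start[i] + (out$end[i] - out$start[i]) %/% 2L
    inA <- which(aS0 <= mid0 & mid0 < aE0)
    if (!length(inA)) next
    if (length(inA) > 1L) {
      ovl <- pmin(aE0[inA], out$end[i]) - pmax(aS0[inA], out$start[i])
      inA <- inA[order(-ovl, aS0[inA])]
    }
    j <- inA[1]
    out$in_alu[i] <- TRUE
    out$alu_id[i] <- mcols(alus)$alu_id[j]
    out$alu_orientation[i] <- mcols(alus)$orientation_class[j]
  }
  out
}

#' Categorise a gene region by where its HSF sites fall
#'
#' @param classified classified-hit data.frame restricted to one
#'   (gene, region kind).
#' @param gene_id,region_kind identifiers for the category record.
#' @return data.frame row with \code{category} one of
#'   \code{alu_and_nonalu}, \code{alu_only}, \code{nonalu_only},
#'   \code{none}.
#' @export
categorizeGene <- function(classified, gene_id, region_kind) {
  sel <- classified$gene_id == gene_id & classified$region_kind == region_kind
  nAlu <- sum(classified$in_alu[sel])
  nNon <- sum(!classified$in_alu[sel])
  category <- if (nAlu >= 1L && nNon >= 1L) "alu_and_nonalu"
    else if (nAlu >= 1L) "alu_only"
    else if (nNon >= 1L) "nonalu_only"
    else "none"
  data.frame(gene_id = gene_id, region_kind = region_kind,
             category = category, n_alu_hits = nAlu, n_nonalu_hits = nNon,
             stringsAsFactors = FALSE)
}

#' Tabulate Alu and HSF-site counts by orientation
#'
#' One row per (expression class, region kind): the number of sense and
#' antisense Alus, the number of in-Alu HSF sites by Alu orientation
#' (occurrence counting), and additionally the number of Alus of each
#' orientation that harbour at least one site (per-Alu view).
#'
#' @param classified classified-hit data.frame over all genes.
#' @param alus host-assigned Alu \code{GRanges} (from [assignAluHosts()] or
#'   [datasetAlus()]).
#' @param genes gene \code{GRanges} with \code{gene_id},
#'   \code{expression_class}.
#' @return data.frame with columns \code{expression_class},
#'   \code{region_kind}, \code{n_sense_alus}, \code{n_antisense_alus},
#'   \code{n_hits_in_sense_alus}, \code{n_hits_in_antisense_alus},
#'   \code{n_sense_alus_with_site}, \code{n_antisense_alus_with_site}.
#' @export
tabulateOrientation <- function(classified, alus, genes) {
  inAlu <- classified[classified$in_alu, , drop = FALSE]
  if (nrow(inAlu) && anyNA(inAlu$alu_orientation))
    .stopf("in-Alu hit with unassigned orientation")
  clsOf <- stats::setNames(mcols(genes)$expression_class,
                           mcols(genes)$gene_id)
  classes <- unique(mcols(genes)$expression_class)
  kinds <- c("upstream5kb", "genic")
  aluCls <- clsOf[mcols(alus)$host_gene]
  hitCls <- clsOf[inAlu$gene_id]
  rows <- list()
  for (cl in classes) for (k in kinds) {
    aSel <- which(aluCls == cl & mcols(alus)$region_kind == k)
    hSel <- which(hitCls == cl & inAlu$region_kind == k)
    ori <- mcols(alus)$orientation_class[aSel]
    hOri <- inAlu$alu_orientation[hSel]
    withSite <- unique(inAlu$alu_id[hSel])
    aluIds <- mcols(alus)$alu_id[aSel]
    rows[[length(rows) + 1L]] <- data.frame(
      expression_class = cl, region_kind = k,
      n_sense_alus = sum(ori == "sense"),
      n_antisense_alus = sum(ori == "antisense"),
      n_hits_in_sense_alus = sum(hOri == "sense"),
      n_hits_in_antisense_alus = sum(hOri == "antisense"),
      n_sense_alus_with_site =
        sum(aluIds %in% withSite & ori == "sense"),
      n_antisense_alus_with_site =
        sum(aluIds %in% withSite & ori == "antisense"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
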