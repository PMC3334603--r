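## 300-base toy Alu consensus bundled with the package: GC-rich arms around
## an A-rich linker, with a B-box-like internal RNA pol III promoter element
## at positions 72-80. Constructed once, offline, under the constraint that
## no window on either strand resembles the default planted HSF motif (best
## chance window scores 5.6 bits against the single-site motif PWM, well
## below the 8.7 operating threshold), so scans of unplanted copies stay
## clean. It is a synthetic stand-in, not a RepBase subfamily consensus.
.TOY_ALU_CONSENSUS <- paste0(
  "CTGCAACAGGGCTCGAACGCTGACGGCGACCCAAGTACTCACCCATAGGACCTACATATTTATCAGGGCC",
  "CGTTCGAGACGTCGCAAGTGAGGGGCGCCGCGAACGAGCCCTGGAAACAGAAAAATACAAAAAACCAACT",
  "GGTGCACAGTGACGCCTGGTTGGCCGAGTCACCCAACTCTCACGACCAGTGCTGAGATCACTCCCGACGC",
  "CCCCATTAGACCCCAGATACGCGCCAGGTAAGTATGAGACGCCGAGGTAAGGCGTCCCTCCCCTTCTGAT",
  "CTAGAAACTGACCCCATTCA")

#' Bundled toy Alu consensus and default HSF motif
#'
#' \code{aluToyConsensus()} returns the 300-base synthetic Alu subfamily
#' consensus bundled with the package; \code{hsfConsensusMotif()} returns
#' the default 13-base HSF heat shock element planted by the generator
#' (a concrete instance of the nCAGAAAGCTCCG-style Alu-internal consensus,
#' with T at the degenerate first position).
#'
#' @return a character string.
#' @export
aluToyConsensus <- function() .TOY_ALU_CONSENSUS

#' @rdname aluToyConsensus
#' @export
hsfConsensusMotif <- function() "TCAGAAAGCTCCG"

#' Configuration for the synthetic Alu/HSF dataset generator
#'
#' Assembles and validates the study conditions the generator embodies:
#' per-class gene counts and Alu insertion rates (down-regulated genes
#' receive the highest genic rate, reproducing the direction of the observed
#' Alu enrichment), orientation-specific motif planting probabilities
#' (antisense Alus are far more likely to carry a site), orientation-specific
#' planting positions on the consensus (221 and 175 for sense, 221 and 91
#' for antisense), and the placement offset of antisense probe signals from
#' planted antisense-Alu sites.
#'
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @param nGenesPerClass named integer vector over classes \code{up},
#'   \code{down}, \code{unchanged}, \code{random}.
#' @param geneLengthKb length-2 numeric range (kb) genic lengths are drawn
#'   from uniformly.
#' @param upstreamLen upstream window length in bases (default 5000).
#' @param aluRatePerKb named per-class Poisson rate of Alu insertions per kb
#'   of region, applied to upstream and genic regions alike.
#' @param aluConsensus consensus sequence used to spawn Alu copies (default
#'   the bundled toy consensus; a user-supplied RepBase consensus may be
#'   substituted).
#' @param aluMutationRate per-base substitution probability applied to each
#'   Alu copy (default 0.05, a typical divergence for young subfamilies).
#' @param indelRate per-base insertion/deletion probability (default 0:
#'   full-length copies only).
#' @param motifPlantProbSense,motifPlantProbAntisense probability that an
#'   Alu of the given orientation carries a planted motif (defaults 0.04 and
#'   0.21, the observed per-orientation site loads).
#' @param plantPositions list with elements \code{sense} and
#'   \code{antisense}: 1-based consensus positions planting is drawn from.
#' @param motif the 13-mer planted (default [hsfConsensusMotif()]).
#' @param backgroundGc GC fraction of non-Alu background sequence
#'   (default 0.41).
#' @param antisenseSignalOffsetKb distance (kb) from a planted antisense-Alu
#'   site to its emitted probe signal, measured in the antisense
#'   transcript's downstream direction (default 2).
#' @param subfamilies subfamily names assigned to Alu copies; all share
#'   \code{aluConsensus} as their reference sequence.
#' @param protectMotifs when \code{TRUE} (default) motifs are planted after
#'   copy mutation, so the planted 13-mer is never degraded.
#' @return validated configuration list (class \code{"syntheticConfig"}).
#' @seealso [generateDataset()]
#' @export
syntheticConfig <- function(seed = 1L,
                            nGenesPerClass = c(up = 50L, down = 50L,
                                               unchanged = 50L, random = 50L),
                            geneLengthKb = c(4, 10),
                            upstreamLen = 5000L,
                            aluRatePerKb = c(up = 0.4, down = 0.6,
                                             unchanged = 0.3, random = 0.3),
                            aluConsensus = aluToyConsensus(),
                            aluMutationRate = 0.05,
                            indelRate = 0,
                            motifPlantProbSense = 0.04,
                            motifPlantProbAntisense = 0.21,
                            plantPositions = list(sense = c(221L, 175L),
                                                  antisense = c(221L, 91L)),
                            motif = hsfConsensusMotif(),
                            backgroundGc = 0.41,
                            antisenseSignalOffsetKb = 2,
                            subfamilies = c("AluY", "AluSx", "AluJb"),
                            protectMotifs = TRUE) {
  classes <- c("up", "down", "unchanged", "random")
  if (!all(classes %in% names(nGenesPerClass)))
    .stopf("nGenesPerClass must name all of: %s", paste(classes, collapse = ", "))
  if (!all(classes %in% names(aluRatePerKb)))
    .stopf("aluRatePerKb must name all of: %s", paste(classes, collapse = ", "))
  if (any(aluRatePerKb < 0)) .stopf("Alu rates must be >= 0")
  .checkProb(c(aluMutationRate, indelRate, motifPlantProbSense,
               motifPlantProbAntisense, backgroundGc),
             "mutation/indel/planting/GC parameters")
  aluConsensus <- toupper(as.character(aluConsensus))
  motif <- toupper(as.character(motif))
  if (nchar(aluConsensus) < nchar(motif))
    .stopf("consensus (%d nt) shorter than the motif (%d nt)",
           nchar(aluConsensus), nchar(motif))
  if (grepl("[^ACGT]", motif)) .stopf("motif must be over A, C, G, T")
  maxPos <- nchar(aluConsensus) - nchar(motif) + 1L
  pp <- unlist(plantPositions)
  if (any(pp < 1L) || any(pp > maxPos))
    .stopf("plant positions must lie in [1, %d]", maxPos)
  if (upstreamLen < 0 || any(geneLengthKb <= 0))
    .stopf("lengths must be positive")
  cfg <- list(seed = as.integer(seed),
              nGenesPerClass = nGenesPerClass[classes],
              geneLengthKb = sort(as.numeric(geneLengthKb)),
              upstreamLen = as.integer(upstreamLen),
              aluRatePerKb = aluRatePerKb[classes],
              aluConsensus = aluConsensus,
              aluMutationRate = aluMutationRate,
              indelRate = indelRate,
              motifPlantProbSense = motifPlantProbSense,
              motifPlantProbAntisense = motifPlantProbAntisense,
              plantPositions = lapply(plantPositions, as.integer),
              motif = motif,
              backgroundGc = backgroundGc,
              antisenseSignalOffsetKb = as.numeric(antisenseSignalOffsetKb),
              subfamilies = subfamilies,
              protectMotifs = isTRUE(protectMotifs))
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Mutate a sequence with substitutions and indels
#'
#' Every base is substituted independently with probability \code{subRate}
#' (always to a different base, so the expected substitution count is
#' \code{subRate * nchar(seq)}). Independently, with probability
#' \code{indelRate} a position suffers an indel: half the time the base is
#' deleted, half the time a random base is inserted before it. Positions
#' inside \code{protect} windows are left untouched.
#'
#' @param seq character string over A, C, G, T.
#' @param subRate,indelRate per-base event probabilities in [0, 1].
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   first.
#' @param protect optional two-column matrix/data.frame of 1-based
#'   (start, end) windows masked from mutation.
#' @return the mutated character string.
#' @export
mutateSequence <- function(seq, subRate, indelRate = 0, seed = NULL,
                           protect = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  .checkProb(c(subRate, indelRate), "subRate/indelRate")
  .mutateWithMap(seq, subRate, indelRate, protect)$seq
}

## as mutateSequence, but also returns map: 0-based new coordinate of each
## old position (NA where deleted)
.mutateWithMap <- function(seq, subRate, indelRate = 0, protect = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  prot <- logical(L)
  if (!is.null(protect) && NROW(protect) > 0) {
    protect <- as.matrix(protect)
    for (k in seq_len(nrow(protect)))
      prot[max(1L, protect[k, 1]):min(L, protect[k, 2])] <- TRUE
  }
  cur <- match(chars, .BASES)
  doSub <- runif(L) < subRate & !prot & !is.na(cur)
  if (any(doSub)) {
    off <- sample.int(3L, sum(doSub), replace = TRUE)
    chars[doSub] <- .BASES[(cur[doSub] - 1L + off) %% 4L + 1L]
  }
  if (indelRate > 0) {
    u <- runif(L)
    u[prot] <- 1
    del <- u < indelRate / 2
    ins <- u >= indelRate / 2 & u < indelRate
    insBase <- character(L)
    if (any(ins)) insBase[ins] <- .BASES[sample.int(4L, sum(ins), TRUE)]
    counts <- as.integer(ins) + as.integer(!del)
    startNew <- cumsum(c(0L, counts[-L]))
    out <- character(sum(counts))
    out[startNew[ins] + 1L] <- insBase[ins]
    keep <- !del
    out[startNew[keep] + as.integer(ins[keep]) + 1L] <- chars[keep]
    map <- ifelse(del, NA_integer_, startNew + as.integer(ins))
    list(seq = paste(out, collapse = ""), map = map)
  } else {
    list(seq = paste(chars, collapse = ""), map = seq_len(L) - 1L)
  }
}

#' Plant a motif into an Alu copy at a consensus position
#'
#' Replaces the bases of \code{aluSeq} starting at 1-based
#' \code{consensusPosition} with the motif (reverse-complemented when
#' \code{orientation = "reverse"}).
#'
#' @param aluSeq character string.
#' @param motif the word to plant.
#' @param consensusPosition 1-based start position; must satisfy
#'   \code{1 <= pos <= nchar(aluSeq) - nchar(motif) + 1}.
#' @param orientation \code{"forward"} (default) or \code{"reverse"}.
#' @return the modified sequence.
#' @export
plantMotif <- function(aluSeq, motif, consensusPosition,
                       orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  maxPos <- nchar(aluSeq) - nchar(motif) + 1L
  if (consensusPosition < 1L || consensusPosition > maxPos)
    .stopf("consensusPosition %d out of range [1, %d]",
           consensusPosition, maxPos)
  word <- if (orientation == "reverse") .revcomp(motif) else motif
  substr(aluSeq, consensusPosition,
         consensusPosition + nchar(motif) - 1L) <- word
  aluSeq
}

#' Generate a seeded synthetic Alu/HSF dataset
#'
#' Builds one contig per gene (a 5-kb upstream pad plus the genic body, on
#' the side the gene's strand dictates), inserts non-overlapping mutated
#' consensus copies as Alus at the per-class Poisson rate, plants the HSF
#' motif into a fraction of copies at orientation-specific consensus
#' positions, and emits a 100-base antisense probe signal near every planted
#' antisense-Alu site in the genic region of a down-regulated gene. Every
#' planted instance is recorded in the truth table.
#'
#' With \code{sequences = FALSE} only the annotation layer (genes and Alu
#' intervals) is generated, which is sufficient for density studies and far
#' faster; the genome, truth table and signals are then empty.
#'
#' @param config a [syntheticConfig()] object.
#' @param sequences generate sequence-level content (default \code{TRUE}).
#' @return a [SyntheticAluDataset-class].
#' @export
generateDataset <- function(config, sequences = TRUE) {
  if (!inherits(config, "syntheticConfig"))
    config <- do.call(syntheticConfig, config)
  set.seed(config$seed)
  consLen <- nchar(config$aluConsensus)
  motifLen <- nchar(config$motif)
  gcp <- config$backgroundGc
  baseProb <- c((1 - gcp) / 2, gcp / 2, gcp / 2, (1 - gcp) / 2)

  genomes <- character(0)
  geneRows <- list(); aluRows <- list(); truthRows <- list(); sigRows <- list()
  aluN <- 0L; sigN <- 0L

  for (cls in names(config$nGenesPerClass)) {
    nG <- config$nGenesPerClass[[cls]]
    rate <- config$aluRatePerKb[[cls]]
    for (g in seq_len(nG)) {
      geneId <- sprintf("%s_g%03d", cls, g)
      L <- as.integer(round(runif(1, config$geneLengthKb[1],
                                  config$geneLengthKb[2]) * 1000))
      gStrand <- sample(c("+", "-"), 1L)
      contigLen <- config$upstreamLen + L
      if (gStrand == "+") {
        tx <- c(config$upstreamLen + 1L, contigLen)      # 1-based closed
        regions <- list(upstream5kb = c(1L, config$upstreamLen),
                        genic = tx)
      } else {
        tx <- c(1L, L)
        regions <- list(upstream5kb = c(L + 1L, contigLen),
                        genic = tx)
      }
      contig <- if (sequences)
        paste(sample(.BASES, contigLen, TRUE, baseProb), collapse = "") else ""
      placed <- matrix(numeric(0), ncol = 2)   # occupied intervals, 1-based

      for (kind in names(regions)) {
        reg <- regions[[kind]]
        regLen <- reg[2] - reg[1] + 1L
        nAlu <- rpois(1L, rate * regLen / 1000)
        for (a in seq_len(nAlu)) {
          aluStrand <- sample(c("+", "-"), 1L)
          subfam <- sample(config$subfamilies, 1L)
          orient <- if (aluStrand == gStrand) "sense" else "antisense"
          pProb <- if (orient == "sense") config$motifPlantProbSense
                   else config$motifPlantProbAntisense
          doPlant <- runif(1) < pProb
          pos <- NA_integer_
          if (doPlant) {
            pp <- config$plantPositions[[orient]]
            pos <- pp[sample.int(length(pp), 1L)]
          }
          if (sequences) {
            mut <- .mutateWithMap(config$aluConsensus,
                                  config$aluMutationRate, config$indelRate,
                                  protect = NULL)
            copy <- mut$seq
            copyOff <- NA_integer_            # 0-based motif offset in copy
            if (doPlant) {
              if (config$protectMotifs) {
                m <- mut$map[pos]
                if (is.na(m)) {
                  cand <- mut$map[pos:length(mut$map)]
                  m <- cand[!is.na(cand)][1]
                }
                if (!is.na(m) && m + motifLen <= nchar(copy)) {
                  copy <- plantMotif(copy, config$motif, m + 1L)
                  copyOff <- m
                } else doPlant <- FALSE
              } else {
                planted <- plantMotif(config$aluConsensus, config$motif, pos)
                mut2 <- .mutateWithMap(planted, config$aluMutationRate,
                                       config$indelRate)
                copy <- mut2$seq
                copyOff <- mut2$map[pos]
                if (is.na(copyOff)) doPlant <- FALSE
              }
            }
            wc <- nchar(copy)
          } else wc <- consLen
          if (regLen < wc) next
          ## rejection placement, non-overlapping
          s1 <- NA_integer_
          for (try in 1:50) {
            cand <- reg[1] + sample.int(regLen - wc + 1L, 1L) - 1L
            if (!nrow(placed) ||
                all(cand + wc - 1L < placed[, 1] | cand > placed[, 2])) {
              s1 <- cand; break
            }
          }
          if (is.na(s1)) next
          placed <- rbind(placed, c(s1, s1 + wc - 1L))
          aluN <- aluN + 1L
          aluId <- sprintf("alu%05d", aluN)
          aluRows[[aluN]] <- data.frame(
            chrom = geneId, start = s1, end = s1 + wc - 1L,
            strand = aluStrand, alu_id = aluId, subfamily = subfam,
            host_gene = geneId, orientation_class = orient,
            region_kind = kind, stringsAsFactors = FALSE)
          if (sequences) {
            oriented <- if (aluStrand == "+") copy else .revcomp(copy)
            substr(contig, s1, s1 + wc - 1L) <- oriented
            if (doPlant && !is.na(copyOff)) {
              a0 <- s1 - 1L                    # 0-based Alu start on contig
              g0 <- if (aluStrand == "+") a0 + copyOff
                    else a0 + (wc - copyOff - motifLen)
              truthRows[[length(truthRows) + 1L]] <- data.frame(
                gene_id = geneId, alu_id = aluId, subfamily = subfam,
                region_kind = kind, orientation = orient,
                consensus_position = pos, strand = aluStrand,
                motif = config$motif, motif_start0 = g0,
                stringsAsFactors = FALSE)
              ## antisense probe signal for genic antisense sites of
              ## down-regulated genes, offset in the antisense transcript's
              ## downstream direction (opposite the host strand)
              if (cls == "down" && orient == "antisense" && kind == "genic") {
                off <- as.integer(round(config$antisenseSignalOffsetKb * 1000))
                if (gStrand == "+") {
                  sEnd0 <- g0 - off            # signal end (0-based, excl)
                  sStart0 <- sEnd0 - 100L
                } else {
                  sStart0 <- g0 + motifLen + off
                  sEnd0 <- sStart0 + 100L
                }
                ## clamp into the genic region
                lo0 <- regions$genic[1] - 1L; hi0 <- regions$genic[2]
                if (sStart0 < lo0) { sStart0 <- lo0; sEnd0 <- lo0 + 100L }
                if (sEnd0 > hi0)   { sEnd0 <- hi0; sStart0 <- hi0 - 100L }
                if (sStart0 >= lo0 && sEnd0 <= hi0) {
                  sigN <- sigN + 1L
                  sigRows[[sigN]] <- data.frame(
                    chrom = geneId, start0 = sStart0, end0 = sEnd0,
                    strand = if (gStrand == "+") "-" else "+",
                    signal_id = sprintf("as%05d", sigN), gene_id = geneId,
                    detection_p = runif(1, 0, 0.04),
                    truth_alu_id = aluId, stringsAsFactors = FALSE)
                }
              }
            }
          }
        }
      }
      genomes[geneId] <- contig
      geneRows[[geneId]] <- data.frame(
        chrom = geneId, tx_start = tx[1], tx_end = tx[2], strand = gStrand,
        gene_id = geneId, expression_class = cls, contig_len = contigLen,
        stringsAsFactors = FALSE)
    }
  }

  geneDf <- do.call(rbind, geneRows)
  seqlens <- geneDf$contig_len
  names(seqlens) <- geneDf$gene_id
  genes <- GRanges(geneDf$chrom,
                   IRanges(geneDf$tx_start, geneDf$tx_end),
                   strand = geneDf$strand, seqlengths = seqlens)
  mcols(genes)$gene_id <- geneDf$gene_id
  mcols(genes)$expression_class <- geneDf$expression_class

  if (length(aluRows)) {
    aluDf <- do.call(rbind, aluRows)
    alus <- GRanges(aluDf$chrom, IRanges(aluDf$start, aluDf$end),
                    strand = aluDf$strand,
                    seqlengths = seqlens[unique(geneDf$gene_id)])
    mcols(alus) <- aluDf[, c("alu_id", "subfamily", "host_gene",
                             "orientation_class", "region_kind")]
  } else {
    alus <- GRanges(seqlengths = seqlens)
  }

  if (length(sigRows)) {
    sigDf <- do.call(rbind, sigRows)
    sigs <- GRanges(sigDf$chrom, IRanges(sigDf$start0 + 1L, sigDf$end0),
                    strand = sigDf$strand, seqlengths = seqlens)
    mcols(sigs) <- sigDf[, c("signal_id", "gene_id", "detection_p",
                             "truth_alu_id")]
  } else {
    sigs <- GRanges(seqlengths = seqlens)
  }

  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(gene_id = character(0), alu_id = character(0),
               subfamily = character(0), region_kind = character(0),
               orientation = character(0), consensus_position = integer(0),
               strand = character(0), motif = character(0),
               motif_start0 = integer(0), stringsAsFactors = FALSE)

  consensus <- DNAStringSet(stats::setNames(
    rep(config$aluConsensus, length(config$subfamilies)),
    config$subfamilies))

  genome <- if (sequences) DNAStringSet(genomes) else
    DNAStringSet(stats::setNames(rep("", length(genomes)), names(genomes)))

  new("SyntheticAluDataset", genome = genome, genes = genes, alus = alus,
      antisenseSignals = sigs, consensus = consensus, truth = truth,
      config = unclass(config))
}
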