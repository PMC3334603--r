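#' HSF position weight matrix
#'
#' S4 container for the 13-column (by default) HSF motif model: base counts,
#' pseudocounted frequencies, log-odds (log base 2 of frequency over
#' background), the background composition and the pseudocount used.
#'
#' @slot counts 4 x width matrix of base tallies, rows A, C, G, T.
#' @slot frequencies 4 x width matrix; each column sums to 1.
#' @slot logOdds 4 x width matrix, \code{log2(frequencies / background)}.
#' @slot background length-4 probability vector, sums to 1.
#' @slot pseudocount non-negative scalar added per base during frequency
#'   estimation.
#'
#' @seealso [buildPWM()], [scanRegion()], [gibbsSampleMotif()]
#' @exportClass HSFMotifModel
setClass("HSFMotifModel",
  representation(
    counts      = "matrix",
    frequencies = "matrix",
    logOdds     = "matrix",
    background  = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("HSFMotifModel", function(object) {
  w <- ncol(object@frequencies)
  msg <- character(0)
  for (nm in c("counts", "frequencies", "logOdds")) {
    m <- slot(object, nm)
    if (nrow(m) != 4L || ncol(m) != w)
      msg <- c(msg, sprintf("%s must be a 4 x %d matrix", nm, w))
    if (!identical(rownames(m), .BASES))
      msg <- c(msg, sprintf("%s rows must be named A, C, G, T", nm))
  }
  if (w < 1L) msg <- c(msg, "width must be >= 1")
  if (length(msg) == 0L) {
    if (any(abs(colSums(object@frequencies) - 1) > 1e-9))
      msg <- c(msg, "frequency columns must each sum to 1")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
      msg <- c(msg, "background must be 4 probabilities summing to 1")
    lo <- log2(object@frequencies / object@background)
    ok <- is.infinite(object@logOdds) & is.infinite(lo) |
      abs(object@logOdds - lo) < 1e-6
    if (!all(ok))
      msg <- c(msg, "logOdds inconsistent with frequencies and background")
    if (length(object@pseudocount) != 1L || object@pseudocount < 0)
      msg <- c(msg, "pseudocount must be a non-negative scalar")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HSFMotifModel motif width (number of columns)
#' @param x,object an \code{HSFMotifModel}
#' @export
motifWidth <- function(x) ncol(x@frequencies)

#' @describeIn HSFMotifModel base count matrix
#' @export
motifCounts <- function(x) x@counts

#' @describeIn HSFMotifModel pseudocounted frequency matrix
#' @export
motifFrequencies <- function(x) x@frequencies

#' @describeIn HSFMotifModel log2 odds matrix
#' @export
motifLogOdds <- function(x) x@logOdds

#' @describeIn HSFMotifModel background base composition
#' @export
motifBackground <- function(x) x@background

setMethod("show", "HSFMotifModel", function(object) {
  cat(sprintf("HSFMotifModel of width %d (pseudocount %.3g)\n",
              motifWidth(object), object@pseudocount))
  cat(sprintf("  consensus: %s\n", consensusString(object)))
  cat(sprintf("  max attainable score: %.2f bits\n",
              sum(apply(object@logOdds, 2, max))))
})

#' Synthetic Alu/HSF dataset
#'
#' S4 container for one simulated study: a genome (one contig per gene),
#' gene models with expression classes, Alu annotations, antisense probe
#' signals, the subfamily consensus sequences used to spawn the Alu copies,
#' and a truth table of every planted motif instance.
#'
#' Genomic ranges follow the usual Bioconductor 1-based closed convention;
#' the truth table records 0-based half-open motif coordinates (column
#' \code{motif_start0}) to match the scanner's hit frame.
#'
#' @slot genome \code{DNAStringSet}, one contig per gene, named by gene id.
#' @slot genes \code{GRanges} of transcript intervals with
#'   \code{gene_id}, \code{expression_class} metadata.
#' @slot alus \code{GRanges} of Alu copies with \code{alu_id},
#'   \code{subfamily}, \code{host_gene}, \code{orientation_class},
#'   \code{region_kind} metadata.
#' @slot antisenseSignals \code{GRanges} of 100-base probe intervals with
#'   \code{signal_id}, \code{gene_id}, \code{detection_p} metadata.
#' @slot consensus \code{DNAStringSet} keyed by subfamily name.
#' @slot truth data.frame of planted motif instances.
#' @slot config the validated generator configuration (list).
#'
#' @seealso [generateDataset()], [syntheticConfig()]
#' @exportClass SyntheticAluDataset
setClass("SyntheticAluDataset",
  representation(
    genome           = "DNAStringSet",
    genes            = "GRanges",
    alus             = "GRanges",
    antisenseSignals = "GRanges",
    consensus        = "DNAStringSet",
    truth            = "data.frame",
    config           = "list"
  )
)

setValidity("SyntheticAluDataset", function(object) {
  msg <- character(0)
  tr <- object@truth
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      contig <- as.character(object@genome[[tr$gene_id[i]]])
      word <- substr(contig, tr$motif_start0[i] + 1L, tr$motif_start0[i] + 13L)
      if (tr$strand[i] == "-") word <- .revcomp(word)
      if (!identical(word, tr$motif[i])) {
        msg <- c(msg, sprintf(
          "truth row %d: motif not retrievable at recorded coordinates", i))
        break
      }
    }
  }
  if (length(object@alus) && length(object@genome) &&
      all(width(object@genome) > 0)) {
    lens <- width(object@genome)
    names(lens) <- names(object@genome)
    bad <- end(object@alus) > lens[as.character(seqnames(object@alus))]
    if (any(bad)) msg <- c(msg, "Alu interval extends beyond its contig")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticAluDataset genome sequences
#' @param x,object a \code{SyntheticAluDataset}
#' @export
datasetGenome <- function(x) x@genome

#' @describeIn SyntheticAluDataset gene models
#' @export
datasetGenes <- function(x) x@genes

#' @describeIn SyntheticAluDataset Alu annotations
#' @export
datasetAlus <- function(x) x@alus

#' @describeIn SyntheticAluDataset antisense probe signals
#' @export
datasetSignals <- function(x) x@antisenseSignals

#' @describeIn SyntheticAluDataset planted-motif truth table
#' @export
datasetTruth <- function(x) x@truth

#' @describeIn SyntheticAluDataset subfamily consensus sequences
#' @export
datasetConsensus <- function(x) x@consensus

setMethod("show", "SyntheticAluDataset", function(object) {
  cls <- table(mcols(object@genes)$expression_class)
  cat(sprintf(
    "SyntheticAluDataset: %d genes (%s), %d Alus, %d planted motifs, %d antisense signals\n",
    length(object@genes),
    paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
    length(object@alus), nrow(object@truth),
    length(object@antisenseSignals)))
})
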