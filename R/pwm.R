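#' Build an HSF position weight matrix from aligned sites
#'
#' Tallies base counts per column over an aligned set of equal-length binding
#' sites, converts to pseudocounted frequencies
#' \eqn{(count + p) / (n + 4p)} and to log2 odds against the background.
#'
#' @param sites character vector or \code{DNAStringSet} of equal-length
#'   sequences over A, C, G, T.
#' @param pseudocount non-negative scalar added per base (default 0.25,
#'   which keeps scores finite for small site sets).
#' @param background length-4 base probability vector in A, C, G, T order
#'   (default uniform).
#' @return an [HSFMotifModel-class] object.
#' @examples
#' pwm <- buildPWM(c("TCAGAAAGCTCCG", "TCAGAAAGCTCCG"), pseudocount = 0)
#' consensusString(pwm)
#' @export
buildPWM <- function(sites, pseudocount = 0.25,
                     background = rep(0.25, 4)) {
  sites <- as.character(sites)
  if (length(sites) < 1L) .stopf("need at least one site")
  w <- unique(nchar(sites))
  if (length(w) != 1L) .stopf("sites must all have the same length")
  if (any(grepl("[^ACGTacgt]", sites)))
    .stopf("sites must contain only A, C, G, T")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
    .stopf("background must be 4 probabilities summing to 1")
  if (length(pseudocount) != 1L || pseudocount < 0)
    .stopf("pseudocount must be a non-negative scalar")
  cm <- consensusMatrix(DNAStringSet(toupper(sites)))[.BASES, , drop = FALSE]
  n <- length(sites)
  freq <- (cm + pseudocount) / (n + 4 * pseudocount)
  bg <- as.numeric(background)
  lo <- log2(freq / bg)
  dimnames(freq) <- dimnames(lo) <- dimnames(cm) <- list(.BASES, NULL)
  new("HSFMotifModel", counts = cm, frequencies = freq, logOdds = lo,
      background = bg, pseudocount = as.numeric(pseudocount))
}

#' Score a single word against a PWM
#'
#' The score is the sum over columns of the log2-odds entry for the observed
#' base: \eqn{\sum_i \log_2(f_{b_i,i} / q_{b_i})}. Words containing an
#' ambiguous base return \code{NA} (they are skipped during scanning).
#'
#' @param pwm an [HSFMotifModel-class].
#' @param word character string of length equal to the motif width.
#' @return numeric score in bits (possibly \code{-Inf} at pseudocount 0;
#'   \code{NA} for ambiguous words).
#' @export
scoreWindow <- function(pwm, word) {
  w <- motifWidth(pwm)
  if (nchar(word) != w)
    .stopf("word length %d does not match motif width %d", nchar(word), w)
  idx <- .seqToIndex(word)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm@logOdds[cbind(idx, seq_len(w))])
}

## log-odds matrix for scoring the minus strand in the plus frame:
## entry [b, j] scores plus-strand base b at window column j when the hit is
## read 5'->3' on the minus strand (complement rows, reverse columns)
.rcLogOdds <- function(lo) {
  m <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(m) <- .BASES
  m
}

#' Scan a region for motif hits on one or both strands
#'
#' Slides the PWM over every window of the sequence and retains windows
#' scoring at or above the threshold. Minus-strand hits are reported in
#' plus-strand coordinates of the scanned region with the matched word read
#' 5'->3' on the minus strand. Windows containing an ambiguous base (N) are
#' skipped. Overlapping hits are all retained.
#'
#' @param pwm an [HSFMotifModel-class].
#' @param sequence character string or \code{DNAString} over A, C, G, T, N.
#' @param threshold minimum retained score in bits (default 8.7, the
#'   operating point calibrated so that the documented HSPA1A promoter site,
#'   scoring 8.9, is retained).
#' @param strands \code{"both"} (default), \code{"plus"} or \code{"minus"}.
#' @param region_id identifier copied into the output.
#' @return data.frame with columns \code{region_id}, \code{start} (0-based),
#'   \code{end} (half-open, \code{start + width}), \code{strand},
#'   \code{score}, \code{matched_word}; sorted by start, then strand
#'   (\code{+} first).
#' @export
scanRegion <- function(pwm, sequence, threshold = 8.7,
                       strands = c("both", "plus", "minus"),
                       region_id = "region") {
  strands <- match.arg(strands)
  if (!is.finite(threshold)) .stopf("threshold must be finite")
  s <- toupper(as.character(sequence))
  w <- motifWidth(pwm)
  empty <- data.frame(region_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), matched_word = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(s) < w) return(empty)
  idx <- .seqToIndex(s)
  out <- list()
  if (strands %in% c("both", "plus")) {
    sc <- .windowScores(pwm@logOdds, idx, w)
    keep <- which(!is.na(sc) & sc >= threshold)
    if (length(keep))
      out$plus <- data.frame(start = keep - 1L, strand = "+",
                             score = sc[keep], stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "minus")) {
    sc <- .windowScores(.rcLogOdds(pwm@logOdds), idx, w)
    keep <- which(!is.na(sc) & sc >= threshold)
    if (length(keep))
      out$minus <- data.frame(start = keep - 1L, strand = "-",
                              score = sc[keep], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  word <- substring(s, hits$start + 1L, hits$start + w)
  word[hits$strand == "-"] <- .revcomp(word[hits$strand == "-"])
  data.frame(region_id = region_id, start = hits$start,
             end = hits$start + w, strand = hits$strand,
             score = hits$score, matched_word = unname(word),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn buildPWM IUPAC-free consensus string: per column, the
#'   majority base if its frequency reaches \code{degeneracyCutoff},
#'   otherwise lowercase \code{"n"}.
#' @param x an \code{HSFMotifModel}.
#' @param degeneracyCutoff frequency needed to print a base letter,
#'   in (0.25, 1] (default 0.5).
#' @param ... ignored.
#' @exportMethod consensusString
setMethod("consensusString", "HSFMotifModel",
  function(x, degeneracyCutoff = 0.5, ...) {
    if (degeneracyCutoff <= 0.25 || degeneracyCutoff > 1)
      .stopf("degeneracyCutoff must be in (0.25, 1]")
    f <- x@frequencies
    top <- apply(f, 2, which.max)
    fmax <- f[cbind(top, seq_len(ncol(f)))]
    paste(ifelse(fmax >= degeneracyCutoff, .BASES[top], "n"), collapse = "")
  })

#' Write / read a PWM as plain text
#'
#' The format is a tab-separated table of per-position base frequencies with
#' an `A C G T` header, preceded by comment lines recording the background
#' and pseudocount, and followed by the raw counts (also commented) so the
#' object round-trips exactly.
#'
#' @param pwm an [HSFMotifModel-class].
#' @param path file path.
#' @return \code{writePWM} returns \code{path} invisibly; \code{readPWM}
#'   returns an \code{HSFMotifModel}.
#' @export
writePWM <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# background\t%s",
                     paste(format(pwm@background, digits = 17), collapse = "\t")),
             con)
  writeLines(sprintf("# pseudocount\t%s",
                     format(pwm@pseudocount, digits = 17)), con)
  for (b in .BASES)
    writeLines(sprintf("# counts_%s\t%s", b,
                       paste(format(pwm@counts[b, ], digits = 17),
                             collapse = "\t")), con)
  writeLines(paste(c("pos", .BASES), collapse = "\t"), con)
  for (j in seq_len(motifWidth(pwm)))
    writeLines(paste(c(j, format(pwm@frequencies[, j], digits = 17)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writePWM
#' @export
readPWM <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  val <- function(key) {
    ln <- meta[startsWith(meta, paste0("# ", key))]
    as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]][-1])
  }
  bg <- val("background")
  pc <- val("pseudocount")
  counts <- do.call(rbind, lapply(.BASES, function(b) val(paste0("counts_", b))))
  counts <- matrix(as.numeric(counts), nrow = 4,
                   dimnames = list(.BASES, NULL))
  n <- max(colSums(counts))
  freq <- (counts + pc) / (n + 4 * pc)
  new("HSFMotifModel", counts = counts, frequencies = freq,
      logOdds = log2(freq / bg), background = bg, pseudocount = pc)
}

#' Write motif hits as BED6 plus a full-precision TSV
#'
#' BED intervals are 0-based half-open with the matched word as the name and
#' the score field set to the log-odds score times 100, rounded.
#'
#' @param hits a hit data.frame from [scanRegion()] (or with genomic
#'   \code{chrom}/\code{start}/\code{end} columns).
#' @param bedPath,tsvPath output paths (either may be \code{NULL} to skip).
#' @return invisible \code{NULL}.
#' @export
writeHits <- function(hits, bedPath = NULL, tsvPath = NULL) {
  chrom <- if ("chrom" %in% names(hits)) hits$chrom else hits$region_id
  if (!is.null(bedPath)) {
    bed <- data.frame(chrom = chrom, start = hits$start, end = hits$end,
                      name = hits$matched_word,
                      score = round(hits$score * 100),
                      strand = hits$strand)
    write.table(bed, bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsvPath))
    write.table(hits, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
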