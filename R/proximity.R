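#' Filter antisense probe signals by detection p-value
#'
#' Retains signals with \code{detection_p} strictly below \code{alpha}.
#'
#' @param signals \code{GRanges} (with a \code{detection_p} metadata column)
#'   or data.frame with a \code{detection_p} column.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @return the retained subset, same container as the input.
#' @export
filterDetected <- function(signals, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must be in (0, 1)")
  if (is(signals, "GRanges"))
    signals[mcols(signals)$detection_p < alpha]
  else signals[signals$detection_p < alpha, , drop = FALSE]
}

## non-negative gap between two 0-based half-open intervals (0 if they
## overlap or abut)
.intervalGap <- function(aStart, aEnd, bStart, bEnd) {
  pmax(0L, pmax(aStart, bStart) - pmin(aEnd, bEnd))
}

#' Nearest Alu-harboured HSF site to an antisense signal
#'
#' Among the supplied sites (in-Alu hits in antisense-oriented Alus of the
#' signal's host gene), picks the one with the smallest edge-to-edge gap
#' (ties to the smaller start). The \code{side} is expressed in the
#' antisense transcript's frame, whose direction opposes the host strand:
#' for a plus-strand host a site at higher coordinates than the signal is
#' \emph{upstream} of the antisense transcript; for a minus-strand host,
#' lower coordinates are upstream. Overlapping pairs are labelled by the
#' midpoint comparison (ties upstream).
#'
#' @param signal one-row data.frame (or list) with 0-based half-open
#'   \code{start}/\code{end} and \code{signal_id}, \code{gene_id}.
#' @param sites classified-hit data.frame rows with genomic 0-based
#'   \code{start}/\code{end} and \code{gene_id}.
#' @param hostStrand strand of the host (sense) gene.
#' @param threshold proximity threshold in bases (default 5000, the 5-kb
#'   flanking rule).
#' @return one-row data.frame with \code{gap}, \code{side},
#'   \code{within_threshold}, site coordinates; or \code{NULL} when
#'   \code{sites} is empty.
#' @export
nearestSite <- function(signal, sites, hostStrand, threshold = 5000L) {
  if (is.null(sites) || !NROW(sites)) return(NULL)
  if (!all(sites$gene_id == signal$gene_id))
    .stopf("site from a different gene than the signal")
  gaps <- .intervalGap(signal$start, signal$end, sites$start, sites$end)
  j <- order(gaps, sites$start)[1]
  sMid <- (signal$start + signal$end) / 2
  hMid <- (sites$start[j] + sites$end[j]) / 2
  side <- if (hostStrand == "+") {
    if (hMid >= sMid) "upstream_of_antisense" else "downstream_of_antisense"
  } else {
    if (hMid <= sMid) "upstream_of_antisense" else "downstream_of_antisense"
  }
  data.frame(signal_id = signal$signal_id, gene_id = signal$gene_id,
             signal_start = signal$start, signal_end = signal$end,
             site_start = sites$start[j], site_end = sites$end[j],
             site_alu_id = sites$alu_id[j], gap = gaps[j], side = side,
             within_threshold = gaps[j] <= threshold,
             stringsAsFactors = FALSE)
}

#' Summarise signal-to-site proximity records
#'
#' @param records data.frame of [nearestSite()] rows.
#' @param binWidth histogram bin width in bases (default 500).
#' @param threshold proximity threshold (default 5000).
#' @return list: \code{n_signals}, \code{n_within} (gap <= threshold),
#'   \code{n_upstream}/\code{n_downstream} (within-threshold records by
#'   side), \code{histogram} (data.frame bin_start, count over all records)
#'   and \code{modal_bin} (bin start with the highest count, smallest on
#'   ties; \code{NA} when empty).
#' @export
proximitySummary <- function(records, binWidth = 500L, threshold = 5000L) {
  if (is.null(records) || !NROW(records))
    return(list(n_signals = 0L, n_within = 0L, n_upstream = 0L,
                n_downstream = 0L,
                histogram = data.frame(bin_start = integer(0),
                                       count = integer(0)),
                modal_bin = NA_integer_))
  within <- records$gap <= threshold
  bins <- (records$gap %/% binWidth) * binWidth
  tab <- table(bins)
  hist <- data.frame(bin_start = as.integer(names(tab)),
                     count = as.integer(tab))
  hist <- hist[order(hist$bin_start), , drop = FALSE]
  rownames(hist) <- NULL
  modal <- hist$bin_start[order(-hist$count, hist$bin_start)][1]
  list(n_signals = nrow(records),
       n_within = sum(within),
       n_upstream = sum(within &
                          records$side == "upstream_of_antisense"),
       n_downstream = sum(within &
                            records$side == "downstream_of_antisense"),
       histogram = hist,
       modal_bin = modal)
}
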