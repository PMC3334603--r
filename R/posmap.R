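#' Local alignment of an Alu copy against its subfamily consensus
#'
#' Smith-Waterman local alignment with affine gaps (via
#' \code{Biostrings::pairwiseAlignment}), defaults match +2, mismatch -3,
#' gap open 8, gap extend 1. The returned column pairs are the 0-based
#' (query offset, subject offset) of every match/mismatch column of the
#' alignment, strictly increasing in both coordinates.
#'
#' @param query Alu copy sequence, oriented 5'->3' on the Alu's own strand.
#' @param subject subfamily consensus sequence.
#' @param match,mismatch substitution scores.
#' @param gapOpen,gapExtend non-negative gap penalties.
#' @param query_id,subject_id identifiers carried in the result.
#' @return list of class \code{"LocalAlignment"}: \code{columns} (two-column
#'   integer matrix \code{q}, \code{s}), \code{identity}, \code{score},
#'   \code{query_id}, \code{subject_id}.
#' @export
localAlign <- function(query, subject, match = 2, mismatch = -3,
                       gapOpen = 8, gapExtend = 1,
                       query_id = "query", subject_id = "subject") {
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  if (!nchar(query) || !nchar(subject)) .stopf("empty sequence")
  sm <- matrix(mismatch, 4, 4, dimnames = list(.BASES, .BASES))
  diag(sm) <- match
  pa <- pairwiseAlignment(query, subject, type = "local",
                          substitutionMatrix = sm,
                          gapOpening = gapOpen, gapExtension = gapExtend)
  p <- strsplit(as.character(alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(alignedSubject(pa)), "")[[1]]
  qoff <- start(pattern(pa)) - 1L
  soff <- start(subject(pa)) - 1L
  qpos <- spos <- integer(length(p))
  q <- qoff; z <- soff
  nmatch <- 0L; ncols <- 0L
  cols <- matrix(NA_integer_, length(p), 2, dimnames = list(NULL, c("q", "s")))
  for (i in seq_along(p)) {
    pg <- p[i] == "-"; sg <- s[i] == "-"
    if (!pg && !sg) {
      ncols <- ncols + 1L
      cols[ncols, ] <- c(q, z)
      nmatch <- nmatch + (p[i] == s[i])
    }
    if (!pg) q <- q + 1L
    if (!sg) z <- z + 1L
  }
  cols <- cols[seq_len(ncols), , drop = FALSE]
  structure(list(query_id = query_id, subject_id = subject_id,
                 columns = cols,
                 identity = if (ncols) nmatch / ncols else 0,
                 score = score(pa)),
            class = "LocalAlignment")
}

#' Project an in-Alu hit onto the subfamily consensus coordinate
#'
#' The hit start is converted to an Alu-local offset on the Alu's own strand
#' (for minus-strand Alus, measured from the Alu's 3' genomic end), then the
#' aligned column pairing that offset gives the 1-based consensus position.
#' When the first hit base falls in a gapped or unaligned query stretch, the
#' nearest aligned column to the right is used; \code{mapped_fraction}
#' records what fraction of the hit's bases lie in aligned columns.
#'
#' @param hit a single classified-hit row (data.frame with genomic 0-based
#'   \code{start}/\code{end}).
#' @param alu the corresponding single-range Alu \code{GRanges}.
#' @param alignment a [localAlign()] result between that Alu copy (oriented
#'   to its own strand) and its subfamily consensus.
#' @return one-row data.frame with \code{consensus_position} (1-based),
#'   \code{orientation}, \code{mapped_fraction}; or \code{NULL} when no hit
#'   base is covered by the alignment.
#' @export
mapHitToConsensus <- function(hit, alu, alignment) {
  if (length(alu) != 1L) .stopf("alu must be a single range")
  aS0 <- start(alu) - 1L
  aE0 <- end(alu)
  if (hit$start < aS0 || hit$end > aE0)
    .stopf("hit lies outside the Alu")
  w <- hit$end - hit$start
  local0 <- if (as.character(strand(alu)) == "+") hit$start - aS0
            else aE0 - hit$end
  cols <- alignment$columns
  covered <- (local0:(local0 + w - 1L)) %in% cols[, "q"]
  if (!any(covered)) return(NULL)
  j <- which(cols[, "q"] >= local0)[1]
  if (is.na(j)) return(NULL)
  data.frame(alu_id = mcols(alu)$alu_id,
             subfamily = alignment$subject_id,
             orientation = mcols(alu)$orientation_class,
             consensus_position = cols[j, "s"] + 1L,
             mapped_fraction = mean(covered),
             stringsAsFactors = FALSE)
}

#' Positional histogram of consensus-mapped hits and its modes
#'
#' Frequency table of consensus positions (per orientation when
#' \code{byOrientation}), plus the modal positions: positions whose count is
#' at least \code{minCount} and is maximal within \code{window} positions on
#' either side (ties resolved to the smallest position).
#'
#' @param mappings data.frame of [mapHitToConsensus()] rows.
#' @param byOrientation split by sense/antisense (default \code{TRUE}).
#' @param minCount minimum count for a mode (default 2).
#' @param window neighbourhood half-width for the local-maximum test
#'   (default 5).
#' @return list with \code{histogram} (data.frame orientation, position,
#'   count) and \code{modes} (same shape, modal rows only).
#' @export
positionHistogram <- function(mappings, byOrientation = TRUE,
                              minCount = 2L, window = 5L) {
  empty <- data.frame(orientation = character(0), position = integer(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (is.null(mappings) || !NROW(mappings))
    return(list(histogram = empty, modes = empty))
  ori <- if (byOrientation) mappings$orientation else "all"
  tab <- as.data.frame(table(orientation = ori,
                             position = mappings$consensus_position),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  hist <- data.frame(orientation = tab$orientation,
                     position = as.integer(tab$position),
                     count = as.integer(tab$Freq), stringsAsFactors = FALSE)
  hist <- hist[order(hist$orientation, hist$position), , drop = FALSE]
  rownames(hist) <- NULL
  modes <- list()
  for (o in unique(hist$orientation)) {
    h <- hist[hist$orientation == o, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      near <- h[abs(h$position - h$position[i]) <= window, , drop = FALSE]
      if (h$count[i] >= minCount &&
          h$count[i] == max(near$count) &&
          h$position[i] == min(near$position[near$count == h$count[i]]))
        modes[[length(modes) + 1L]] <- h[i, , drop = FALSE]
    }
  }
  modes <- if (length(modes)) do.call(rbind, modes) else empty
  rownames(modes) <- NULL
  list(histogram = hist, modes = modes)
}
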