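#' De novo motif discovery by Gibbs site sampling
#'
#' Classic single-site Gibbs sampler: one motif occurrence is assumed per
#' sequence; at each iteration one sequence is held out, a pseudocounted
#' model is rebuilt from the remaining sites, and a new site offset for the
#' held-out sequence is drawn with probability proportional to the model's
#' odds over the background. Sequences are cycled in order, so
#' \code{nIterations} counts single-sequence updates (one sweep =
#' \code{length(sequences)} updates). After sampling, a deterministic polish
#' is applied: a column-phase shift search (all sites moved together by up
#' to \code{maxShift}) followed by one argmax reassignment sweep. The
#' highest information content solution across restarts is returned.
#'
#' @param sequences character vector (or \code{DNAStringSet}) of at least 2
#'   sequences, each at least \code{width} long.
#' @param width motif width (default 13).
#' @param nIterations single-sequence sampling updates per restart
#'   (default 500).
#' @param nRestarts independent restarts (default 25).
#' @param seed integer seed; the sampler is fully deterministic given the
#'   seed.
#' @param pseudocount per-base pseudocount for the sampling model
#'   (default 0.25).
#' @param maxShift phase-shift polish radius in columns (default 3).
#' @return list with elements \code{pwm} (an [HSFMotifModel-class] built
#'   from the final sites), \code{offsets} (0-based site start per
#'   sequence), \code{sites} (the aligned words) and
#'   \code{informationContent} (bits).
#' @export
gibbsSampleMotif <- function(sequences, width = 13L, nIterations = 500L,
                             nRestarts = 25L, seed = 1L,
                             pseudocount = 0.25, maxShift = 3L) {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 2L) .stopf("need at least 2 sequences")
  lens <- nchar(sequences)
  if (any(lens < width))
    .stopf("all sequences must be at least width (%d) long", width)
  idxs <- lapply(sequences, .seqToIndex)
  if (any(vapply(idxs, anyNA, TRUE)))
    .stopf("sequences must contain only A, C, G, T")
  nwin <- lens - width + 1L

  ## background from overall base composition, floored at 0.05 so that
  ## near-monomorphic inputs keep finite, sane log-odds
  tab <- tabulate(unlist(idxs), nbins = 4L)
  bg <- pmax(tab / sum(tab), 0.05)
  bg <- bg / sum(bg)

  siteCols <- function(offsets) {
    ## 4 x width counts over current sites
    cm <- matrix(0L, 4L, width)
    for (i in seq_len(n)) {
      b <- idxs[[i]][(offsets[i] + 1L):(offsets[i] + width)]
      cm[cbind(b, seq_len(width))] <- cm[cbind(b, seq_len(width))] + 1L
    }
    cm
  }
  infoContent <- function(offsets) {
    f <- (siteCols(offsets) + pseudocount) / (n + 4 * pseudocount)
    sum(f * log2(f / bg))
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    offsets <- vapply(nwin, function(m) sample.int(m, 1L) - 1L, 0L)
    cm <- siteCols(offsets)
    for (t in seq_len(nIterations)) {
      z <- (t - 1L) %% n + 1L
      b <- idxs[[z]][(offsets[z] + 1L):(offsets[z] + width)]
      cm[cbind(b, seq_len(width))] <- cm[cbind(b, seq_len(width))] - 1L
      f <- (cm + pseudocount) / (n - 1 + 4 * pseudocount)
      lo <- log2(f / bg)
      sc <- .windowScores(lo, idxs[[z]], width)
      wts <- 2^(sc - max(sc))
      o <- sample.int(nwin[z], 1L, prob = wts) - 1L
      offsets[z] <- o
      b <- idxs[[z]][(o + 1L):(o + width)]
      cm[cbind(b, seq_len(width))] <- cm[cbind(b, seq_len(width))] + 1L
    }
    ## phase-shift polish: move all sites together
    bestShift <- 0L
    bestIC <- infoContent(offsets)
    for (d in setdiff(seq(-maxShift, maxShift), 0L)) {
      shifted <- offsets + d
      if (any(shifted < 0L) || any(shifted > nwin - 1L)) next
      ic <- infoContent(shifted)
      if (ic > bestIC + 1e-12) { bestIC <- ic; bestShift <- d }
    }
    offsets <- offsets + bestShift
    ## one deterministic argmax reassignment sweep
    cm <- siteCols(offsets)
    for (z in seq_len(n)) {
      b <- idxs[[z]][(offsets[z] + 1L):(offsets[z] + width)]
      cm[cbind(b, seq_len(width))] <- cm[cbind(b, seq_len(width))] - 1L
      f <- (cm + pseudocount) / (n - 1 + 4 * pseudocount)
      sc <- .windowScores(log2(f / bg), idxs[[z]], width)
      o <- which.max(sc) - 1L
      offsets[z] <- o
      b <- idxs[[z]][(o + 1L):(o + width)]
      cm[cbind(b, seq_len(width))] <- cm[cbind(b, seq_len(width))] + 1L
    }
    ic <- infoContent(offsets)
    if (is.null(best) || ic > best$informationContent + 1e-12)
      best <- list(offsets = offsets, informationContent = ic)
  }
  sites <- substring(sequences, best$offsets + 1L, best$offsets + width)
  pwm <- buildPWM(sites, pseudocount = pseudocount, background = rep(0.25, 4))
  list(pwm = pwm, offsets = best$offsets, sites = sites,
       informationContent = best$informationContent)
}
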