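## shared fixtures and independent oracles for the test suite

## brute-force scanning oracle: scores every window on both strands with
## scoreWindow(), independently of scanRegion()'s vectorised path
bruteForceScan <- function(pwm, sequence, threshold,
                           strands = "both", region_id = "region") {
  s <- toupper(sequence)
  w <- motifWidth(pwm)
  revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  rows <- list()
  n <- nchar(s) - w + 1L
  if (n >= 1L) for (i in seq_len(n)) {
    word <- substr(s, i, i + w - 1L)
    if (strands %in% c("both", "plus")) {
      sc <- scoreWindow(pwm, word)
      if (!is.na(sc) && sc >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = region_id, start = i - 1L, end = i - 1L + w,
          strand = "+", score = sc, matched_word = word,
          stringsAsFactors = FALSE)
    }
    if (strands %in% c("both", "minus")) {
      rcw <- revcomp(word)
      sc <- scoreWindow(pwm, rcw)
      if (!is.na(sc) && sc >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = region_id, start = i - 1L, end = i - 1L + w,
          strand = "-", score = sc, matched_word = rcw,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(region_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), matched_word = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## hand-written Welch two-sample t-test (independent of stats::t.test)
welchOracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## random ACGT string
randSeq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, p), collapse = "")
}

revcompStr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## small fast synthetic config for smoke tests
smallConfig <- function(seed = 1L, ...) {
  syntheticConfig(seed = seed,
                  nGenesPerClass = c(up = 4L, down = 4L,
                                     unchanged = 4L, random = 4L),
                  ...)
}
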