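test_that("PWM construction matches closed-form pseudocount arithmetic", {
  ## two identical sites, no pseudocount: observed base frequency 1
  pwm <- buildPWM(c("ACGT", "ACGT"), pseudocount = 0)
  expect_equal(unname(motifFrequencies(pwm)["A", 1]), 1)
  expect_equal(unname(motifFrequencies(pwm)["C", 1]), 0)

  ## single site, pseudocount 1: (1+1)/(1+4) = 0.4 observed, 0.2 others
  pwm <- buildPWM("ACGT", pseudocount = 1)
  expect_equal(unname(motifFrequencies(pwm)["A", 1]), 0.4)
  expect_equal(unname(motifFrequencies(pwm)["G", 1]), 0.2)

  ## hand tally: {"AC","AG"} column 2 splits C/G evenly
  pwm <- buildPWM(c("AC", "AG"), pseudocount = 0)
  expect_equal(unname(motifFrequencies(pwm)["C", 2]), 0.5)
  expect_equal(unname(motifFrequencies(pwm)["G", 2]), 0.5)
  expect_equal(unname(motifCounts(pwm)["A", 1]), 2)
})

test_that("PWM construction rejects invalid site sets", {
  expect_error(buildPWM(character(0)), "at least one")
  expect_error(buildPWM(c("ACG", "AC")), "same length")
  expect_error(buildPWM("ACGN"), "only A, C, G, T")
  expect_error(buildPWM("ACGT", pseudocount = -1), "pseudocount")
  expect_error(buildPWM("ACGT", background = c(0.5, 0.5, 0.5, 0.5)),
               "background")
})

test_that("window scoring is the summed log-odds of the word", {
  motif <- "TCAGAAAGCTCCG"
  pwm <- buildPWM(motif, pseudocount = 0)
  ## identity PWM: score of its own site is width * log2(4)
  expect_equal(scoreWindow(pwm, motif), 13 * log2(4))
  ## a base of frequency 0 at pseudocount 0 scores -Inf
  expect_equal(scoreWindow(pwm, "ACAGAAAGCTCCG"), -Inf)
  ## hand sum for the {"AC","AG"} model
  pwm2 <- buildPWM(c("AC", "AG"), pseudocount = 0)
  expect_equal(scoreWindow(pwm2, "AC"), log2(1 / 0.25) + log2(0.5 / 0.25))
  expect_error(scoreWindow(pwm2, "ACG"), "length")
  expect_true(is.na(scoreWindow(pwm2, "AN")))
})

test_that("no word can exceed the column-wise log-odds maxima", {
  set.seed(42)
  for (k in 1:20) {
    sites <- replicate(5, randSeq(9))
    pwm <- buildPWM(sites)
    cap <- sum(apply(motifLogOdds(pwm), 2, max))
    words <- replicate(50, randSeq(9))
    expect_true(all(vapply(words, scoreWindow, 0, pwm = pwm) <= cap + 1e-12))
  }
})

test_that("scanning equals a brute-force enumeration of all windows", {
  set.seed(7)
  motif <- "TCAGAAAGCTCCG"
  pwm <- buildPWM(motif)
  for (k in 1:10) {
    s <- randSeq(500)
    got <- scanRegion(pwm, s, threshold = 4, region_id = "r")
    want <- bruteForceScan(pwm, s, threshold = 4, region_id = "r")
    expect_equal(got, want)
  }
})

test_that("scanning handles short sequences, plants and strand symmetry", {
  motif <- "TCAGAAAGCTCCG"
  pwm <- buildPWM(motif)
  expect_equal(nrow(scanRegion(pwm, randSeq(12))), 0L)

  ## reverse-complement plant at offset 50 comes back as a minus-strand hit
  set.seed(3)
  s <- randSeq(200)
  substr(s, 51, 63) <- revcompStr(motif)
  hits <- scanRegion(pwm, s, threshold = 17)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 50L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$matched_word, motif)

  ## minus-strand scan equals plus-strand scan of the reverse complement,
  ## with coordinates mirrored (start -> len - end)
  set.seed(11)
  for (k in 1:5) {
    s <- randSeq(300)
    minus <- scanRegion(pwm, s, threshold = 5, strands = "minus")
    plus <- scanRegion(pwm, revcompStr(s), threshold = 5, strands = "plus")
    expect_equal(sort(minus$start), sort(nchar(s) - plus$end))
    expect_equal(sort(minus$score), sort(plus$score))
  }

  ## windows containing N are skipped
  s2 <- paste0(strrep("A", 20), "N", strrep("A", 20))
  pwmA <- buildPWM(strrep("A", 13), pseudocount = 0)
  hitsN <- scanRegion(pwmA, s2, threshold = 20, strands = "plus")
  expect_false(any(hitsN$start %in% 8:20))
})

test_that("consensus string renders dominant columns and n elsewhere", {
  ## dominant columns print their base; sub-cutoff columns print n
  pwm <- buildPWM(c("AC", "AG", "AG", "AT"), pseudocount = 0)
  ## column 2 is (C 0.25, G 0.5, T 0.25): at the cutoff it still prints G,
  ## above it the column is degenerate
  expect_equal(consensusString(pwm, degeneracyCutoff = 0.5), "AG")
  expect_equal(consensusString(pwm, degeneracyCutoff = 0.6), "An")
  ## logo-style shape: first column degenerate, the rest dominant
  sites <- c("ACAGAAAGCTCCG", "CCAGAAAGCTCCG", "GCAGAAAGCTCCG",
             "TCAGAAAGCTCCG")
  pwm13 <- buildPWM(sites, pseudocount = 0)
  expect_equal(consensusString(pwm13, degeneracyCutoff = 0.5),
               "nCAGAAAGCTCCG")
  expect_error(consensusString(pwm13, degeneracyCutoff = 0.2), "Cutoff")
})

test_that("PWM text serialisation round-trips", {
  pwm <- buildPWM(c("TCAGAAAGCTCCG", "TCAGAAAGCACCG", "TCAGTAAGCTCCG"),
                  pseudocount = 0.25)
  f <- tempfile(fileext = ".pwm")
  writePWM(pwm, f)
  back <- readPWM(f)
  expect_equal(motifFrequencies(back), motifFrequencies(pwm))
  expect_equal(motifCounts(back), motifCounts(pwm))
  expect_equal(motifBackground(back), motifBackground(pwm))
})
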