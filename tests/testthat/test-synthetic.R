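test_that("zero Alu rate gives an empty annotation and truth table", {
  cfg <- smallConfig(seed = 2,
                     aluRatePerKb = c(up = 0, down = 0, unchanged = 0,
                                      random = 0))
  d <- generateDataset(cfg)
  expect_equal(length(datasetAlus(d)), 0L)
  expect_equal(nrow(datasetTruth(d)), 0L)
  expect_equal(length(datasetGenes(d)), 16L)
})

test_that("identical seeds give byte-identical datasets", {
  a <- generateDataset(smallConfig(seed = 5))
  b <- generateDataset(smallConfig(seed = 5))
  expect_identical(as.character(datasetGenome(a)),
                   as.character(datasetGenome(b)))
  expect_identical(datasetTruth(a), datasetTruth(b))
  expect_identical(as.data.frame(datasetAlus(a)),
                   as.data.frame(datasetAlus(b)))
  expect_identical(as.data.frame(datasetSignals(a)),
                   as.data.frame(datasetSignals(b)))
  c <- generateDataset(smallConfig(seed = 6))
  expect_false(identical(as.character(datasetGenome(a)),
                         as.character(datasetGenome(c))))
})

test_that("forced antisense planting at position 91 is exhaustively recoverable", {
  cfg <- smallConfig(seed = 8, aluMutationRate = 0,
                     motifPlantProbSense = 0,
                     motifPlantProbAntisense = 1,
                     plantPositions = list(sense = 221L, antisense = 91L))
  d <- generateDataset(cfg)
  alus <- datasetAlus(d)
  truth <- datasetTruth(d)
  anti <- alus[mcols(alus)$orientation_class == "antisense"]
  expect_gt(length(anti), 0)
  ## every antisense Alu is in the truth table at consensus position 91
  expect_setequal(truth$alu_id, mcols(anti)$alu_id)
  expect_true(all(truth$consensus_position == 91L))
  ## and carries the exact 13-mer at consensus offset 91 of its own strand
  genome <- datasetGenome(d)
  for (i in seq_along(anti)) {
    a <- anti[i]
    s <- as.character(subseq(genome[[as.character(seqnames(a))]],
                             start(a), end(a)))
    if (as.character(strand(a)) == "-") s <- revcompStr(s)
    expect_identical(substr(s, 91, 103), cfg$motif)
  }
})

test_that("substitution counts follow the configured rate", {
  expect_identical(mutateSequence("ACGTACGT", 0, 0), "ACGTACGT")
  set.seed(31)
  base <- randSeq(10000)
  nsub <- vapply(1:100, function(i) {
    mut <- mutateSequence(base, 0.05)
    sum(strsplit(mut, "")[[1]] != strsplit(base, "")[[1]])
  }, 0)
  ## binomial: mean 500, SE of the mean over 100 seeds
  se <- sqrt(10000 * 0.05 * 0.95 / 100)
  expect_lt(abs(mean(nsub) - 500), 3 * se)
  ## forced indels change the length (each position deletes or inserts)
  set.seed(32)
  expect_false(nchar(mutateSequence("ACGTA", 0, 1)) == 5L)
  ## protected windows are untouched
  set.seed(33)
  mut <- mutateSequence(base, 0.5, protect = cbind(101, 200))
  expect_identical(substr(mut, 101, 200), substr(base, 101, 200))
})

test_that("motif planting respects coordinates and orientation", {
  motif <- hsfConsensusMotif()
  s <- strrep("A", 300)
  expect_identical(substr(plantMotif(s, motif, 1), 1, 13), motif)
  p <- plantMotif(s, motif, 221)
  expect_identical(substr(p, 221, 233), motif)
  ## reverse plant at 91, then reverse-complement the whole sequence:
  ## the motif reads forward at the mirrored position
  r <- plantMotif(s, motif, 91, orientation = "reverse")
  rc <- revcompStr(r)
  expect_equal(as.integer(regexpr(motif, rc, fixed = TRUE)),
               300L - 91L - 13L + 2L)
  expect_error(plantMotif(s, motif, 289), "out of range")
  expect_error(plantMotif(s, motif, 0), "out of range")
})

test_that("generated class-wise Alu densities recover configured rates", {
  cfg <- syntheticConfig(seed = 21,
                         nGenesPerClass = c(up = 250L, down = 250L,
                                            unchanged = 0L, random = 0L),
                         aluRatePerKb = c(up = 0.4, down = 0.6,
                                          unchanged = 0, random = 0))
  d <- generateDataset(cfg, sequences = FALSE)
  regions <- extractRegions(datasetGenes(d))
  dens <- aluDensityTable(datasetAlus(d), regions)
  cls <- setNames(mcols(datasetGenes(d))$expression_class,
                  mcols(datasetGenes(d))$gene_id)
  for (cl in c("up", "down")) {
    v <- dens$value[dens$region_kind == "genic" & cls[dens$gene_id] == cl]
    rate10kb <- cfg$aluRatePerKb[[cl]] * 10      # counts per 10 kb
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - rate10kb), 3 * se)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(smallConfig(motifPlantProbSense = 1.2), "probabilities")
  expect_error(smallConfig(aluRatePerKb = c(up = -1, down = 1,
                                            unchanged = 1, random = 1)),
               ">= 0")
  expect_error(smallConfig(aluConsensus = "ACGTACGT"), "shorter")
  expect_error(smallConfig(plantPositions = list(sense = 500L,
                                                 antisense = 91L)),
               "plant positions")
})
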