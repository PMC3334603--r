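writeBed12 <- function(df, path) {
  bed <- data.frame(df$chrom, df$start, df$end, df$name, 0L, df$strand,
                    df$start, df$end, "0", 1L,
                    paste0(df$end - df$start, ","), "0,")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

test_that("gene loading filters ambiguous-assembly chromosomes and joins classes", {
  bed <- tempfile(fileext = ".bed")
  writeBed12(data.frame(
    chrom = c("chr1", "chr1_random", "chr6_hap2", "chr2"),
    start = c(1000L, 1000L, 1000L, 5000L),
    end = c(9000L, 9000L, 9000L, 15000L),
    name = c("gA", "gB", "gC", "gD"),
    strand = c("+", "+", "-", "-")), bed)
  cls <- tempfile(fileext = ".tsv")
  write.table(data.frame(c("gA", "gD"), c("up", "down")), cls,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  genes <- loadGeneModels(bed, cls)
  expect_setequal(mcols(genes)$gene_id, c("gA", "gD"))
  expect_equal(mcols(genes)$expression_class[
    mcols(genes)$gene_id == "gD"], "down")
  ## BED 0-based half-open -> GRanges 1-based closed
  expect_equal(start(genes[mcols(genes)$gene_id == "gA"]), 1001L)
  expect_equal(end(genes[mcols(genes)$gene_id == "gA"]), 9000L)

  ## class defaults to unchanged without a table
  genes2 <- loadGeneModels(bed)
  expect_true(all(mcols(genes2)$expression_class == "unchanged"))

  ## duplicate gene ids are an error
  dup <- tempfile(fileext = ".bed")
  writeBed12(data.frame(chrom = "chr1", start = c(0L, 100L),
                        end = c(50L, 200L), name = c("g", "g"),
                        strand = "+"), dup)
  expect_error(loadGeneModels(dup), "duplicate")
  expect_error(loadGeneModels(tempfile(fileext = ".bed")), "not found")
})

test_that("refFlat parsing reports malformed rows with their line number", {
  rf <- tempfile()
  writeLines(c("GENEA\tnmA\tchr1\t+\t1000\t9000\t1000\t9000",
               "GENEB\tnmB\tchr2\t-\tbroken\t9000\t1000\t9000"), rf)
  expect_error(loadGeneModels(rf, format = "refflat"), "line 2")
  writeLines("GENEA\tnmA\tchr1\t+\t1000\t9000\t1000\t9000", rf)
  g <- loadGeneModels(rf, format = "refflat")
  expect_equal(start(g), 1001L)
  expect_equal(as.character(strand(g)), "+")
})

test_that("analysis regions follow the host strand and truncate at edges", {
  genes <- GRanges("chr1", IRanges(10001, 20000), strand = "+",
                   seqlengths = c(chr1 = 30000))
  mcols(genes)$gene_id <- "g1"
  mcols(genes)$expression_class <- "up"
  regs <- extractRegions(genes)
  up <- regs[mcols(regs)$kind == "upstream5kb"]
  genic <- regs[mcols(regs)$kind == "genic"]
  expect_equal(c(start(up), end(up)), c(5001L, 10000L))    # [5000,10000)
  expect_equal(c(start(genic), end(genic)), c(10001L, 20000L))

  strand(genes) <- "-"
  regs <- extractRegions(genes)
  up <- regs[mcols(regs)$kind == "upstream5kb"]
  expect_equal(c(start(up), end(up)), c(20001L, 25000L))   # [20000,25000)

  ## truncation at the contig start
  strand(genes) <- "+"
  genes2 <- GRanges("chr1", IRanges(2001, 9000), strand = "+",
                    seqlengths = c(chr1 = 30000))
  mcols(genes2)$gene_id <- "g2"
  up2 <- extractRegions(genes2)
  up2 <- up2[mcols(up2)$kind == "upstream5kb"]
  expect_equal(c(start(up2), end(up2)), c(1L, 2000L))      # length 2000
})

test_that("Alu loading converts dialect conventions and filters families", {
  gr <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges(c(101, 500, 900), c(400, 799, 1199)),
                strand = c("+", "-", "+"))
  mcols(gr)$alu_id <- sprintf("alu%05d", 1:3)
  mcols(gr)$subfamily <- c("AluY", "AluSx", "AluJb")

  for (dialect in c("repeatmasker_out", "bed6")) {
    f <- tempfile()
    writeAlus(gr, f, dialect)
    back <- loadAlus(f, dialect)
    expect_equal(start(back), start(gr))
    expect_equal(end(back), end(gr))
    expect_equal(as.character(strand(back)), as.character(strand(gr)))
    expect_equal(mcols(back)$subfamily, mcols(gr)$subfamily)
  }

  ## .out is 1-based inclusive: begin 101 end 400 is the interval [100,400)
  f <- tempfile()
  writeAlus(gr[1], f, "repeatmasker_out")
  a <- loadAlus(f, "repeatmasker_out")
  expect_equal(start(a) - 1L, 100L)
  expect_equal(end(a), 400L)
  ## orientation C maps to minus strand (exercised by the round trip above)
  expect_true(any(grepl(" C ", readLines({
    f2 <- tempfile(); writeAlus(gr[2], f2, "repeatmasker_out"); f2
  }), fixed = TRUE)))

  ## non-Alu families are excluded by default
  gr2 <- gr
  mcols(gr2)$subfamily <- c("AluY", "L1PA3", "FRAM")
  f3 <- tempfile()
  writeAlus(gr2, f3, "bed6")
  expect_equal(mcols(loadAlus(f3, "bed6"))$subfamily, "AluY")
  expect_setequal(mcols(loadAlus(f3, "bed6",
                                 includeFlam = TRUE))$subfamily,
                  c("AluY", "FRAM"))
})

test_that("orientation classification is the strand comparison", {
  expect_equal(assignAluOrientation("+", "+"), "sense")
  expect_equal(assignAluOrientation("+", "-"), "antisense")
  expect_equal(assignAluOrientation(c("+", "-"), c("-", "-")),
               c("antisense", "sense"))
  expect_error(assignAluOrientation(".", "+"), "strand")
})

test_that("host assignment partitions Alus and matches the generator labels", {
  d <- generateDataset(smallConfig(seed = 13, motifPlantProbSense = 0.5,
                                   motifPlantProbAntisense = 0.5))
  regions <- extractRegions(datasetGenes(d))
  raw <- datasetAlus(d)
  truthMeta <- mcols(raw)
  mcols(raw) <- mcols(raw)[, c("alu_id", "subfamily")]
  hosted <- assignAluHosts(raw, regions)
  ## one assignment per Alu on this one-contig-per-gene layout
  expect_setequal(mcols(hosted)$alu_id, truthMeta$alu_id)
  expect_equal(length(hosted), length(raw))
  m <- match(mcols(hosted)$alu_id, truthMeta$alu_id)
  expect_equal(mcols(hosted)$host_gene, truthMeta$host_gene[m])
  expect_equal(mcols(hosted)$region_kind, truthMeta$region_kind[m])
  expect_equal(mcols(hosted)$orientation_class,
               truthMeta$orientation_class[m])
  ## every assigned Alu overlaps its region by at least one base, and the
  ## sense/antisense sets partition the host-assigned Alus
  key <- paste(mcols(regions)$gene_id, mcols(regions)$kind)
  idx <- match(paste(mcols(hosted)$host_gene, mcols(hosted)$region_kind),
               key)
  ovl <- pmin(end(hosted), end(regions)[idx]) -
    pmax(start(hosted), start(regions)[idx]) + 1L
  expect_true(all(ovl >= 1L))
  expect_true(all(mcols(hosted)$orientation_class %in%
                    c("sense", "antisense")))
})
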