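mkRegion <- function(start1, end1, gene = "g1", kind = "genic",
                     chrom = "chr1", strand = "+", len = 100000) {
  r <- GRanges(chrom, IRanges(start1, end1), strand = strand,
               seqlengths = setNames(len, chrom))
  mcols(r)$gene_id <- gene
  mcols(r)$kind <- kind
  r
}

mkAlus <- function(starts1, ends1, strands = "+", chrom = "chr1",
                   orientation = "sense") {
  a <- GRanges(chrom, IRanges(starts1, ends1), strand = strands)
  mcols(a)$alu_id <- sprintf("alu%05d", seq_along(a))
  mcols(a)$subfamily <- "AluY"
  mcols(a)$orientation_class <- rep(orientation, length.out = length(a))
  a
}

mkHits <- function(starts0, region_id = "r") {
  data.frame(region_id = region_id, start = starts0, end = starts0 + 13L,
             strand = "+", score = 10, matched_word = strrep("A", 13),
             stringsAsFactors = FALSE)
}

test_that("hits are assigned to Alus by the midpoint rule", {
  region <- mkRegion(1, 1000)
  ## region-relative hit [100,113) against Alu [50,400) -> contained
  alus <- mkAlus(51, 400)
  cl <- assignHitsToAlus(mkHits(100L), alus, region)
  expect_true(cl$in_alu)
  expect_equal(cl$alu_id, "alu00001")
  expect_equal(cl$alu_orientation, "sense")
  ## genomic coordinates are region start + offset
  expect_equal(cl$start, 100L)

  ## no overlapping Alu -> non-Alu
  cl <- assignHitsToAlus(mkHits(500L), alus, region)
  expect_false(cl$in_alu)
  expect_true(is.na(cl$alu_id))

  ## hit [100,113): midpoint 106 sits in [106,300), not [0,106)
  twoAlus <- mkAlus(c(1, 107), c(106, 300))
  cl <- assignHitsToAlus(mkHits(100L), twoAlus, region)
  expect_true(cl$in_alu)
  expect_equal(cl$alu_id, "alu00002")

  ## overlapping Alus both containing the midpoint: larger overlap wins
  ovl <- mkAlus(c(95, 103), c(120, 300))
  cl <- assignHitsToAlus(mkHits(100L), ovl, region)
  expect_equal(cl$alu_id, "alu00001")   # covers all 13 bases vs 11

  ## coordinate-frame mismatch errors
  expect_error(assignHitsToAlus(mkHits(995L), alus, region),
               "coordinate frame")
})

test_that("gene categories reflect the hit multiset", {
  cl <- rbind(
    data.frame(gene_id = "g1", region_kind = "genic",
               in_alu = c(TRUE, TRUE, FALSE)),
    data.frame(gene_id = "g2", region_kind = "genic", in_alu = TRUE),
    data.frame(gene_id = "g3", region_kind = "genic", in_alu = FALSE))
  expect_equal(categorizeGene(cl, "g1", "genic")$category, "alu_and_nonalu")
  expect_equal(categorizeGene(cl, "g2", "genic")$category, "alu_only")
  expect_equal(categorizeGene(cl, "g3", "genic")$category, "nonalu_only")
  expect_equal(categorizeGene(cl, "g4", "genic")$category, "none")
})

test_that("orientation tabulation matches a hand count and conserves hits", {
  genes <- GRanges(c("c1", "c2"), IRanges(1, 1000), strand = "+",
                   seqlengths = c(c1 = 2000, c2 = 2000))
  mcols(genes)$gene_id <- c("g1", "g2")
  mcols(genes)$expression_class <- c("down", "up")
  ## g1: 2 sense Alus (1 hit) + 3 antisense Alus (4 hits), all genic
  alus <- GRanges("c1", IRanges(c(1, 101, 201, 301, 401) * 1,
                                c(1, 101, 201, 301, 401) + 50))
  mcols(alus)$alu_id <- sprintf("alu%05d", 1:5)
  mcols(alus)$subfamily <- "AluY"
  mcols(alus)$host_gene <- "g1"
  mcols(alus)$region_kind <- "genic"
  mcols(alus)$orientation_class <- c("sense", "sense", rep("antisense", 3))
  classified <- data.frame(
    gene_id = "g1", region_kind = "genic",
    in_alu = TRUE,
    alu_id = c("alu00001", "alu00003", "alu00003", "alu00004", "alu00005"),
    alu_orientation = c("sense", rep("antisense", 4)),
    stringsAsFactors = FALSE)
  tab <- tabulateOrientation(classified, alus, genes)
  row <- tab[tab$expression_class == "down" & tab$region_kind == "genic", ]
  expect_equal(
    unlist(row[c("n_sense_alus", "n_antisense_alus",
                 "n_hits_in_sense_alus", "n_hits_in_antisense_alus")],
           use.names = FALSE),
    c(2L, 3L, 1L, 4L))
  ## per-Alu presence view: alu00003 carries two sites but counts once
  expect_equal(row$n_antisense_alus_with_site, 3L)
  expect_equal(row$n_sense_alus_with_site, 1L)
  ## hit conservation within the row
  expect_equal(row$n_hits_in_sense_alus + row$n_hits_in_antisense_alus,
               sum(classified$in_alu))
  ## rows with no data are all zero
  up <- tab[tab$expression_class == "up" & tab$region_kind == "genic", ]
  expect_true(all(up[, 3:8] == 0L))
  ## unassigned orientation on an in-Alu hit is an error
  bad <- classified
  bad$alu_orientation[1] <- NA
  expect_error(tabulateOrientation(bad, alus, genes), "orientation")
})

test_that("classification partitions every hit exactly once", {
  res <- runPipeline(pipelineConfig(synthetic = smallConfig(
    seed = 17, motifPlantProbSense = 0.5, motifPlantProbAntisense = 0.5)))
  cl <- res$classified
  expect_true(all(cl$in_alu == !is.na(cl$alu_id)))
  expect_true(all(is.na(cl$alu_orientation) == !cl$in_alu))
  ## category counts over genes with >= 1 hit sum to the number of such genes
  withHits <- unique(cl[, c("gene_id", "region_kind")])
  cats <- res$categories
  expect_equal(sum(cats$category != "none"), nrow(withHits))
})
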