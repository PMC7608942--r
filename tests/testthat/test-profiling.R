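profFixture <- function() {
  genes <- makeGeneTable(data.frame(
    gene_id = c("A|g1", "B|g5", "B|g9", "C|g2", "C|g3"),
    species = c("A", "B", "B", "C", "C"),
    chrom = "chr1", start = c(0L, 0L, 100L, 0L, 100L),
    end = c(50L, 50L, 150L, 50L, 150L), strand = "+",
    exon_count = c(9L, 9L, 1L, 1L, 9L), stringsAsFactors = FALSE))
  comms <- new("CommunitySet", communities = list(
    C1 = c("A|g1", "B|g5"), C2 = c("B|g9", "C|g2")), k = 2L)
  list(genes = genes, comms = comms,
       fam = c("A|g1", "B|g5", "B|g9", "C|g2", "C|g3"))
}

test_that("profile matrix counts genes per community and species", {
  fx <- profFixture()
  pr <- buildProfile(fx$comms, fx$genes, "(A:1,(B:1,C:1):1);", fx$fam)
  expect_equal(colnames(pr$counts), c("A", "B", "C"))
  expect_equal(unname(pr$counts["C1", ]), c(1L, 1L, 0L))
  expect_equal(unname(pr$counts["C2", ]), c(0L, 1L, 1L))
  expect_equal(unname(pr$counts["none", ]), c(0L, 0L, 1L))  # C|g3 unclustered
  expect_equal(pr$presence["C1", "B"], 1L)
  # column sums conserve per-species copy number (no overlap here)
  cn <- copyNumberTable(fx$genes, fx$fam)
  expect_equal(unname(colSums(pr$counts)), cn$copies)
  expect_error(buildProfile(fx$comms, fx$genes, "(A:1,B:1);", fx$fam),
               "missing from tree")
})

test_that("leaf-order permutation permutes profile columns only", {
  fx <- profFixture()
  p1 <- buildProfile(fx$comms, fx$genes, "(A:1,(B:1,C:1):1);", fx$fam)
  p2 <- buildProfile(fx$comms, fx$genes, "((C:1,B:1):1,A:1);", fx$fam)
  expect_equal(colnames(p2$counts), c("C", "B", "A"))
  expect_equal(p2$counts[, colnames(p1$counts)], p1$counts)
})

test_that("copy numbers include zero-copy species and sum to family size", {
  fx <- profFixture()
  cn <- copyNumberTable(fx$genes, c("A|g1", "B|g5"))
  expect_equal(cn$copies[cn$species == "C"], 0L)
  expect_equal(sum(cn$copies), 2L)
})

test_that("exon summaries report mean, median, smallest mode and histogram", {
  genes <- makeGeneTable(data.frame(
    gene_id = paste0("S|g", 1:6), species = "S", chrom = "c1",
    start = (0:5) * 10L, end = (0:5) * 10L + 5L, strand = "+",
    exon_count = c(9L, 9L, 9L, 8L, 1L, 2L), stringsAsFactors = FALSE))
  comms <- new("CommunitySet", communities = list(
    C1 = paste0("S|g", 1:4)), k = 3L)
  es <- exonSummary(comms, genes, familyIds = paste0("S|g", 1:6))
  s1 <- es$summary[es$summary$group == "C1", ]
  expect_equal(s1$mean, 8.75)
  expect_equal(s1$mode, 9L)
  expect_equal(sum(es$histograms$C1), s1$n)
  # mode ties resolve to the smallest value
  comms2 <- new("CommunitySet", communities = list(
    C1 = paste0("S|g", c(1, 4, 5, 6))), k = 3L)  # exons 9,8,1,2: all tied
  es2 <- exonSummary(comms2, genes, familyIds = paste0("S|g", 1:6))
  expect_equal(es2$summary$mode[es2$summary$group == "C1"], 1L)
  # absent exon annotation is an actionable error
  bare <- makeGeneTable(data.frame(
    gene_id = "S|g1", species = "S", chrom = "c1", start = 0L, end = 5L,
    strand = "+", stringsAsFactors = FALSE))
  expect_error(exonSummary(comms, bare), "GFF3")
})
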