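test_that("anchor sets group hits by chromosome pair with ranks", {
  genes <- makeGeneTable(data.frame(
    gene_id = c("A|g1", "A|g2", "B|h1", "B|h2"), species = c("A", "A", "B", "B"),
    chrom = c("chr1", "chr2", "chr2", "chr2"),
    start = c(0L, 0L, 0L, 100L), end = c(50L, 50L, 50L, 150L),
    strand = "+", stringsAsFactors = FALSE))
  hits <- data.frame(query_id = c("A|g1", "B|h1"),
                     subject_id = c("B|h2", "B|h2"),
                     bitscore = c(100, 90), evalue = 1e-30)
  sets <- buildAnchorSets(genes, hits)
  expect_setequal(names(sets), c("A.chr1|B.chr2", "B.chr2|B.chr2"))
  a <- sets[["A.chr1|B.chr2"]]
  expect_equal(a$i, 0L)   # rank of A|g1 on A.chr1
  expect_equal(a$j, 1L)   # rank of B|h2 on B.chr2
  # same-chromosome anchor listed once with i < j
  s <- sets[["B.chr2|B.chr2"]]
  expect_equal(nrow(s), 1L)
  expect_lt(s$i, s$j)
  expect_equal(length(buildAnchorSets(genes, hits[0, ])), 0L)
})

test_that("chaining reproduces hand-derived blocks", {
  p <- chainParams()
  # perfect diagonal: one forward block, 5 anchors, score 250
  anc <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                    i = 1:5, j = 1:5)
  cb <- chainAnchors(anc, p)
  expect_equal(nrow(blocks(cb)), 1L)
  expect_equal(blocks(cb)$orientation, "forward")
  expect_equal(blocks(cb)$score, 250)
  expect_equal(blocks(cb)$n_anchors, 5L)

  # below the minimum block length: nothing
  cb4 <- chainAnchors(anc[1:4, ], p)
  expect_equal(nrow(blocks(cb4)), 0L)

  # one gap: 3 * 50 + (-1) * 1 = 149
  anc3 <- data.frame(gene_a = paste0("a", 1:3), gene_b = paste0("b", 1:3),
                     i = c(1, 2, 4), j = c(1, 2, 3))
  cb3 <- chainAnchors(anc3, chainParams(match_size = 3))
  expect_equal(blocks(cb3)$score, 149)

  # anti-diagonal: one inverted block of 5
  anci <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                     i = 1:5, j = 5:1)
  cbi <- chainAnchors(anci, p)
  expect_equal(blocks(cbi)$orientation, "inverted")
  expect_equal(blocks(cbi)$n_anchors, 5L)
})

test_that("DP best chain equals exhaustive monotone-subsequence search", {
  set.seed(202)
  p <- chainParams(match_size = 2L, max_gaps = 5L)
  for (rep in 1:30) {
    anc <- randomAnchors(sample(3:10, 1), L = 12L)
    oracle <- chainOracleScore(anc, p)
    got <- chainAnchors(anc, p)
    b <- blocks(got)
    dp_best <- if (nrow(b)) max(b$score) else NA
    # the first extracted chain is the maximum-score chain
    if (!is.na(dp_best)) expect_equal(b$score[1], oracle)
    else expect_lte(oracle, p@match_score * (p@match_size - 1))
  }
})

test_that("emitted blocks always satisfy the block invariants", {
  set.seed(303)
  for (rep in 1:10) {
    anc <- randomAnchors(sample(10:40, 1), L = 30L)
    cb <- chainAnchors(anc, chainParams(match_size = 3L, max_gaps = 10L))
    expect_true(validateBlocks(cb))
  }
})

test_that("tandem detection flags close same-chromosome homologs", {
  genes <- makeGeneTable(data.frame(
    gene_id = paste0("S|g", 1:7), species = "S", chrom = "chr1",
    start = (0:6) * 100L, end = (0:6) * 100L + 50L, strand = "+",
    stringsAsFactors = FALSE))
  # ranks: g1..g7 = 0..6
  hits <- data.frame(
    query_id = c("S|g5", "S|g5", "S|g6", "S|g1", "S|g2"),
    subject_id = c("S|g6", "S|g7", "S|g7", "S|g3", "S|g3"),
    bitscore = 100, evalue = 1e-30)
  td <- detectTandems(genes, hits, window = 1)
  # adjacent homologs (ranks 4,5) and (5,6) are tandem; |4-6|=2 is not;
  # g1-g3 (ranks 0,2) is not
  expect_setequal(paste(td$pairs$gene_a, td$pairs$gene_b),
                  c("S|g5 S|g6", "S|g6 S|g7", "S|g2 S|g3"))
  # three consecutive homologs form one array of size 3
  sizes <- lengths(td$arrays)
  expect_equal(sort(sizes), c(2L, 3L))
  expect_true(any(vapply(td$arrays, function(a)
    setequal(a, c("S|g5", "S|g6", "S|g7")), NA)))
})

test_that("all-pairs run covers n(n+1)/2 comparisons and is order-invariant", {
  genes <- combineGeneTables(list(
    twoSpeciesGenes(8),
    makeGeneTable(data.frame(
      gene_id = paste0("C|g", 1:8), species = "C", chrom = "chr1",
      start = (0:7) * 100L, end = (0:7) * 100L + 50L, strand = "+"))))
  hits <- rbind(orthoHits(8),
                data.frame(query_id = paste0("A|g", 1:8),
                           subject_id = paste0("C|g", 1:8),
                           bitscore = 300, evalue = 1e-40),
                data.frame(query_id = paste0("B|g", 1:8),
                           subject_id = paste0("C|g", 1:8),
                           bitscore = 300, evalue = 1e-40))
  res <- runAllPairs(genes, hits)
  expect_equal(nrow(res$manifest), 3 * 4 / 2)  # n(n+1)/2 with n = 3
  expect_equal(sum(res$manifest$n_blocks), 3L)

  # permuting input row order changes nothing
  g2 <- makeGeneTable(geneRecords(genes)[sample.int(24), ])
  res2 <- runAllPairs(g2, hits[sample.int(nrow(hits)), ])
  expect_identical(blocks(res$blocks), blocks(res2$blocks))

  # single genome, no duplicated families: one self comparison, no blocks
  a_only <- makeGeneTable(
    geneRecords(twoSpeciesGenes(8))[1:8, , drop = FALSE])
  solo <- runAllPairs(a_only, orthoHits(8)[0, ])
  expect_equal(nrow(solo$manifest), 1L)
  expect_equal(sum(solo$manifest$n_blocks), 0L)

  dup <- list(twoSpeciesGenes(4), twoSpeciesGenes(4))
  expect_error(runAllPairs(dup, orthoHits(4)), "duplicate species")
})
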