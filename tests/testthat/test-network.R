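makeBlockFixture <- function() {
  genes <- twoSpeciesGenes(8)
  runAllPairs(genes, orthoHits(8))
}

test_that("network assembly: one edge per unordered anchor pair", {
  res <- makeBlockFixture()
  net <- buildNetwork(res$blocks, twoSpeciesGenes(8))
  expect_equal(nrow(networkEdges(net)), 8L)  # one block of 8 anchors
  expect_equal(nrow(networkNodes(net)), 16L)
  # handshake lemma
  expect_equal(sum(nodeDegrees(net)), 2L * nrow(networkEdges(net)))
  expect_true(validObject(net))
  # empty block set -> empty network
  empty <- chainAnchors(NULL, chainParams())
  e <- buildNetwork(empty, twoSpeciesGenes(8))
  expect_equal(nrow(networkEdges(e)), 0L)
})

test_that("a pair anchored in two blocks yields one annotated edge", {
  # two chromosome pairs can't share an anchor, so synthesize block sets
  bs <- new("CollinearBlockSet",
            blocks = data.frame(
              block_id = c("b1", "b2"), species_a = "A", chrom_a = "c1",
              species_b = "B", chrom_b = "c1", orientation = "forward",
              score = c(250, 250), n_anchors = c(5L, 5L)),
            anchors = rbind(
              data.frame(block_id = "b1", gene_a = paste0("A|g", 1:5),
                         gene_b = paste0("B|g", 1:5), i = 1:5, j = 1:5),
              data.frame(block_id = "b2", gene_a = paste0("A|g", 3:7),
                         gene_b = paste0("B|g", 3:7), i = 3:7, j = 3:7)),
            params = chainParams())
  net <- buildNetwork(bs, twoSpeciesGenes(8))
  e <- networkEdges(net)
  expect_equal(nrow(e), 7L)
  shared <- e$block_ids[e$node1 == "A|g3"]
  expect_equal(shared, "b1;b2")
  expect_error(buildNetwork(bs, twoSpeciesGenes(2)), "absent")
})

test_that("family subnetwork is the induced subgraph with isolated members", {
  res <- makeBlockFixture()
  genes <- twoSpeciesGenes(8)
  net <- buildNetwork(res$blocks, genes)
  fam <- c("A|g2", "B|g2", "A|g5")  # A|g5's partner B|g5 not in family
  sub <- extractFamilySubnetwork(net, fam, genes)
  e <- networkEdges(sub)
  expect_equal(nrow(e), 1L)
  expect_setequal(c(e$node1, e$node2), c("A|g2", "B|g2"))
  # isolated family member kept as degree-0 node
  expect_true("A|g5" %in% networkNodes(sub)$node)
  expect_equal(unname(nodeDegrees(sub)["A|g5"]), 0L)
  # extraction is idempotent and never grows the edge set
  sub2 <- extractFamilySubnetwork(sub, fam, genes)
  expect_identical(networkEdges(sub2), networkEdges(sub))
  expect_lte(nrow(networkEdges(sub)), nrow(networkEdges(net)))
  # disjoint family: warning, no edges
  expect_warning(none <- extractFamilySubnetwork(net, c("Z|g1"), NULL),
                 "no family gene")
  expect_equal(nrow(networkEdges(none)), 0L)
})

test_that("block context returns whole blocks touching the family", {
  res <- makeBlockFixture()
  ctx <- blockContext(res$blocks, "A|g3")
  expect_equal(length(ctx), 1L)
  expect_equal(nrow(ctx[[1]]), 8L)  # the whole block, not just family anchors
  expect_equal(length(blockContext(res$blocks, "Z|none")), 0L)
})
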