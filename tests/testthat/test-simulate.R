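noEventConfig <- function(seed = 1L, tree = "((A:1,B:1):1,C:2);") {
  simConfig(tree = tree, n_chromosomes = 1L, genes_per_chromosome = 10L,
            cds_codons = 30L, seed = seed)
}

test_that("no-event limit: all species identical to the root in order/content", {
  sim <- simulateDataset(noEventConfig())
  g <- geneRecords(sim@genes)
  per <- split(g, g$species)
  expect_equal(length(per), 3L)
  fams <- lapply(per, function(x)
    sim@truth$families$family[match(x$gene_id[order(x$rank)],
                                    sim@truth$families$gene_id)])
  expect_equal(fams$A, fams$B)
  expect_equal(fams$A, fams$C)
  expect_equal(unname(vapply(per, nrow, 0L)), rep(10L, 3))
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulateDataset(mammalScenario(5L))
  s2 <- simulateDataset(mammalScenario(5L))
  expect_identical(geneRecords(s1@genes), geneRecords(s2@genes))
  expect_identical(s1@cds, s2@cds)
  expect_identical(s1@hits, s2@hits)
  expect_identical(s1@truth, s2@truth)
  s3 <- simulateDataset(mammalScenario(6L))
  expect_false(identical(s1@cds, s3@cds))
})

test_that("WGD with full retention exactly doubles descendant gene counts", {
  cfg <- simConfig(tree = "(A:1,B:1)anc;", genes_per_chromosome = 10L,
                   cds_codons = 30L,
                   wgd_events = list(list(branch = "root", multiplicity = 2,
                                          retention_prob = 1)))
  sim <- simulateDataset(cfg)
  g <- geneRecords(sim@genes)
  expect_equal(unname(table(g$species)["A"]), 20L, ignore_attr = TRUE)
  expect_error(applyEvent(rootGenome(noEventConfig()), "wgd",
                          multiplicity = 4), "multiplicity")
})

test_that("event mechanics: tandem insertion, transposition, inversion", {
  cfg <- noEventConfig()
  set.seed(1)
  genome <- rootGenome(cfg)
  # tandem copy lands immediately after its parent; later genes shift
  g2 <- applyEvent(genome, "tandem", target = "g5")
  expect_equal(nrow(g2), 11L)
  expect_equal(which(g2$family == "fam5"), c(5L, 6L))
  expect_equal(g2$context[6], g2$context[5])
  # rna transposition: single-exon copy in a fresh context, relaxed rate
  g3 <- applyEvent(genome, "transposition", target = "g5", rna = TRUE,
                   relaxed_multiplier = 2)
  copy <- g3[g3$family == "fam5" & g3$id != "g5", ]
  expect_equal(copy$exon, 1L)
  expect_equal(copy$mult, 2)
  expect_match(copy$context, "^ctxT")
  expect_equal(g3$exon[g3$id == "g5"], 9L)   # donor untouched
  # dna transposition preserves exon count
  g4 <- applyEvent(genome, "transposition", target = "g5", rna = FALSE)
  copy4 <- g4[g4$family == "fam5" & g4$id != "g5", ]
  expect_equal(copy4$exon, 9L)
  # inversion reverses order and flips strands inside the window
  g5 <- applyEvent(genome, "inversion", chrom = 1L, window = c(3L, 6L))
  expect_equal(g5$id[3:6], genome$id[6:3])
  expect_equal(g5$strand[3:6], rep("-", 4))
  expect_error(applyEvent(genome, "inversion", chrom = 1L,
                          window = c(8L, 20L)), "window")
  # loss closes ranks
  g6 <- applyEvent(genome, "loss", target = "g5")
  expect_equal(nrow(g6), 9L)
  expect_false("g5" %in% g6$id)
})

test_that("WGD duplicate retention follows the binomial law", {
  cfg <- simConfig(tree = "(A:1,B:1)anc;", n_chromosomes = 2L,
                   genes_per_chromosome = 500L, cds_codons = 5L)
  set.seed(99)
  genome <- rootGenome(cfg)
  g2 <- applyEvent(genome, "wgd", multiplicity = 2, retention_prob = 0.5)
  retained <- nrow(g2) - 1000L
  # Binomial(1000, 0.5): mean 500, sd ~ 15.8; assert within 3 sigma
  expect_lt(abs(retained - 500), 3 * sqrt(1000 * 0.25))
})

test_that("gene order stays a valid rank permutation through event storms", {
  cfg <- simConfig(tree = "(A:1,B:1)anc;", genes_per_chromosome = 20L,
                   cds_codons = 10L, loss_rate = 0.1, tandem_rate = 0.1,
                   transposition_rate = 0.05, inversion_rate = 0.1,
                   protect_focal = FALSE, seed = 11L)
  sim <- simulateDataset(cfg)
  expect_true(validObject(sim@genes))  # rank permutation enforced there
})

test_that("synonymous evolution: identity at zero, protein invariance", {
  set.seed(3)
  cds <- randomCdsSeq(50)
  expect_identical(evolveCds(cds, 0), cds)
  for (d in c(0.2, 1.0)) {
    child <- evolveCds(cds, d)
    expect_identical(translateCds(child), translateCds(cds))
  }
  expect_error(evolveCds("ATGTAAAAA", 0.1), "stop")
})

test_that("true distances are symmetric, additive and track the multiplier", {
  sim <- simulateDataset(mammalScenario(9L))
  d <- sim@truth$distances
  fam <- familyMembers(sim)
  dd <- d[d$gene_a %in% fam & d$gene_b %in% fam, ]
  expect_true(all(dd$d_true >= 0))
  ctx <- sim@truth$contexts
  transposed <- ctx$gene_id[ctx$gene_id %in% fam &
                              grepl("^ctxT", ctx$context)]
  conserved <- setdiff(fam, transposed)
  within <- function(set) {
    rows <- dd$gene_a %in% set & dd$gene_b %in% set
    mean(dd$d_true[rows])
  }
  # relaxed (transposed) copies diverge faster than the conserved set
  expect_gt(within(transposed), within(conserved))
  # ortholog pairs of the untouched focal copy inside the clade diverged
  # at the radiation: exactly two terminal branches at ks_rate 0.25
  ing <- grep("^OUT", grep("\\|g20$", fam, value = TRUE), value = TRUE,
              invert = TRUE)
  expect_equal(within(ing), 0.5, tolerance = 1e-9)
})

test_that("mammal scenario truth: two contexts in the clade, outgroup in one", {
  sim <- simulateDataset(mammalScenario(4L))
  fam <- familyMembers(sim)
  ctx <- sim@truth$contexts
  fctx <- ctx[ctx$gene_id %in% fam, ]
  sp <- sub("\\|.*", "", fctx$gene_id)
  expect_equal(length(unique(fctx$context[sp != "OUT"])), 2L)
  out_ctx <- unique(fctx$context[sp == "OUT"])
  expect_equal(length(out_ctx), 1L)
  expect_true(out_ctx %in% fctx$context[sp != "OUT"])
})

test_that("simulated homology is exactly the within-family pair set", {
  sim <- simulateDataset(noEventConfig(seed = 8L))
  fams <- sim@truth$families
  n_per_family <- table(fams$family)
  expect_equal(nrow(sim@hits), sum(countPairs(as.integer(n_per_family))))
  f <- setNames(fams$family, fams$gene_id)
  expect_true(all(f[sim@hits$query_id] == f[sim@hits$subject_id]))
  # bitscore decreases with true distance
  d <- sim@truth$distances
  key <- paste(d$gene_a, d$gene_b)
  hb <- sim@hits[match(key, paste(sim@hits$query_id, sim@hits$subject_id)), ]
  expect_true(cor(hb$bitscore, d$d_true, method = "spearman") <= 0)
})

test_that("dataset files round-trip through the standard formats", {
  sim <- simulateDataset(noEventConfig(seed = 12L))
  dir <- withr::local_tempdir()
  writeDataset(sim, dir)
  gt <- readGff3(file.path(dir, "A.gff3"), species = "A")
  orig <- geneRecords(sim@genes)
  orig <- orig[orig$species == "A", ]
  got <- geneRecords(gt)
  expect_equal(got$start, orig$start)
  expect_equal(got$end, orig$end)
  expect_equal(got$exon_count, orig$exon_count)
  cds <- readFasta(file.path(dir, "A.cds.fa"))
  expect_identical(unname(cds), unname(sim@cds[names(cds)]))
  hits <- readHomologyTable(file.path(dir, "homology.tsv"))
  expect_equal(nrow(hits), nrow(sim@hits))
})
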