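test_that("protein alignment: identity score, symmetry, gap placement", {
  id <- alignProteins("MKV", "MKV")
  expect_equal(id$score, 14)           # BLOSUM62 diagonal: 5 + 5 + 4
  expect_equal(id$a1, "MKV")
  ab <- alignProteins("MKVLL", "MKL")
  ba <- alignProteins("MKL", "MKVLL")
  expect_equal(ab$score, ba$score)
  gap <- alignProteins("MKV", "MV")
  expect_equal(nchar(gap$a1), 3L)
  expect_equal(sum(strsplit(gap$a2, "")[[1]] == "-"), 1L)
  expect_error(alignProteins("MK1", "MK"), "non-amino-acid")
})

test_that("back-translation maps residues to codons and gaps to ---", {
  aln <- list(a1 = "MK-V", a2 = "MKAV")
  ca <- backtranslate(aln, "ATGAAAGTT", "ATGAAAGCTGTT")
  expect_equal(ca$codon1, "ATGAAA---GTT")
  expect_equal(ca$codon2, "ATGAAAGCTGTT")
  # terminal stop is stripped before the length check
  ca2 <- backtranslate(aln, "ATGAAAGTTTAA", "ATGAAAGCTGTT")
  expect_equal(ca2$codon1, "ATGAAA---GTT")
  expect_error(backtranslate(aln, "ATGAAAGTT", "ATGAAAGGGGTT"),
               "does not match protein")
  expect_error(backtranslate(list(a1 = "MKV", a2 = "MKV"),
                             "ATGTAAGTT", "ATGAAAGTT"), "stop")
})

test_that("NG86 reproduces hand-counted site and difference values", {
  # identical sequences
  z <- ng86("ATGAAA", "ATGAAA")
  expect_equal(z$Sd, 0); expect_equal(z$Nd, 0)
  expect_equal(z$Ks, 0); expect_equal(z$Ka, 0)
  expect_false(z$saturated)
  # glycine runs: third positions fully synonymous
  e <- ng86("GGGGGGGGG", "GGAGGGGGG")
  expect_equal(e$S, 3)
  expect_equal(e$N, 6)
  expect_equal(e$Sd, 1)
  expect_equal(e$Nd, 0)
  expect_equal(e$ps, 1 / 3)
  expect_equal(e$Ks, -0.75 * log(1 - 4 / 9))
  expect_equal(e$Ka, 0)
  # single two-fold codon saturates: ps = 1 / (1/3) = 3 > 3/4
  s <- ng86("TTT", "TTC")
  expect_equal(s$S, 1 / 3)
  expect_equal(s$Sd, 1)
  expect_true(s$saturated)
  expect_true(is.na(s$Ks))
})

test_that("NG86 invariants: symmetry, site closure, additivity", {
  set.seed(808)
  for (rep in 1:10) {
    a <- randomCdsSeq(40)
    b <- evolveCds(a, 0.3)
    e1 <- ng86(a, b)
    e2 <- ng86(b, a)
    expect_equal(e1, e2)
    expect_equal(e1$S + e1$N, 3 * e1$n_codons)
  }
  a1 <- randomCdsSeq(30); b1 <- evolveCds(a1, 0.2)
  a2 <- randomCdsSeq(25); b2 <- evolveCds(a2, 0.6)
  part1 <- ng86(a1, b1); part2 <- ng86(a2, b2)
  whole <- ng86(paste0(a1, a2), paste0(b1, b2))
  expect_equal(whole$Sd, part1$Sd + part2$Sd)
  expect_equal(whole$Nd, part1$Nd + part2$Nd)
  expect_equal(whole$S, part1$S + part2$S)
  expect_equal(whole$N, part1$N + part2$N)
})

test_that("codons with gaps or ambiguity are excluded from counts", {
  expect_message(e <- ng86("ATG---AAA", "ATGGGGAAA"), "excluding")
  expect_equal(e$n_codons, 2L)
  expect_equal(e$n_excluded, 1L)
  expect_error(suppressMessages(ng86("---", "GGG")), "no comparable")
})

test_that("pair counting matches the closed form", {
  expect_equal(countPairs(60), 1770)
  expect_equal(countPairs(73), 2628)
  expect_equal(countPairs(1), 0)
  expect_equal(countPairs(0), 0)
})

test_that("group Ks: per-pair table size, zero baseline, small groups", {
  set.seed(909)
  cds <- setNames(vapply(1:6, function(i) randomCdsSeq(40), ""),
                  paste0("g", 1:6))
  same <- setNames(rep(cds[1], 4), paste0("s", 1:4))
  out <- suppressWarnings(groupKs(
    list(G = names(cds), H = names(same), tiny = "g1"),
    c(cds, same)))
  expect_equal(sum(out$pairs$group == "G"), countPairs(6))
  expect_equal(out$summary$mean_ks[out$summary$group == "H"], 0)
  expect_false("tiny" %in% out$summary$group)
  expect_warning(groupKs(list(tiny = "g1"), cds), "fewer than 2")
  # quartile ordering invariant
  sG <- out$summary[out$summary$group == "G", ]
  expect_true(sG$q1_ks <= sG$median_ks && sG$median_ks <= sG$q3_ks)
})

test_that("faster-evolving syntelog groups show larger Ks", {
  set.seed(910)
  root <- randomCdsSeq(120)
  conserved <- setNames(vapply(1:4, function(i) evolveCds(root, 0.25), ""),
                        paste0("c", 1:4))
  relaxed <- setNames(vapply(1:4, function(i) evolveCds(root, 0.55), ""),
                      paste0("r", 1:4))
  res <- groupKs(list(cons = names(conserved), rel = names(relaxed)),
                 c(conserved, relaxed))
  s <- res$summary
  expect_gt(s$mean_ks[s$group == "rel"], s$mean_ks[s$group == "cons"])
})
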