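edgeDf <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(node1 = m[, 1], node2 = m[, 2], stringsAsFactors = FALSE)
}

test_that("clique percolation on hand-worked graphs", {
  # single triangle
  tri <- edgeDf("a", "b", "b", "c", "a", "c")
  expect_equal(communityList(findCommunities(tri, 3)),
               list(C1 = c("a", "b", "c")))
  # path: no triangle, no community
  path <- edgeDf("a", "b", "b", "c")
  expect_equal(length(findCommunities(path, 3)), 0L)
  # triangles sharing an edge merge
  merged <- edgeDf("a", "b", "b", "c", "a", "c", "b", "d", "c", "d")
  expect_equal(communityList(findCommunities(merged, 3)),
               list(C1 = c("a", "b", "c", "d")))
  # triangles sharing only one node stay separate; the node overlaps
  overlap <- edgeDf("a", "b", "b", "c", "a", "c",
                    "c", "d", "d", "e", "c", "e")
  cl <- communityList(findCommunities(overlap, 3))
  expect_equal(length(cl), 2L)
  expect_true(all(vapply(cl, function(m) "c" %in% m, NA)))
  expect_error(findCommunities(tri, 1), "k must be")
})

test_that("clique percolation equals the brute-force oracle on random graphs", {
  set.seed(404)
  for (rep in 1:50) {
    edges <- randomEdges(sample(6:18, 1), runif(1, 0.1, 0.5))
    if (nrow(edges) == 0) next
    k <- sample(3:4, 1)
    got <- canonCommunities(unname(communityList(findCommunities(edges, k))))
    expect_identical(got, cpmOracle(edges, k))
  }
})

test_that("communities at k+1 nest inside communities at k", {
  set.seed(505)
  for (rep in 1:20) {
    edges <- randomEdges(15, 0.4)
    ck <- communityList(findCommunities(edges, 3))
    ck1 <- communityList(findCommunities(edges, 4))
    for (m in ck1)
      expect_true(any(vapply(ck, function(big) all(m %in% big), NA)))
  }
})

test_that("adding an edge never splits an existing community", {
  set.seed(606)
  for (rep in 1:10) {
    edges <- randomEdges(12, 0.3)
    if (nrow(edges) < 2) next
    before <- communityList(findCommunities(edges, 3))
    nodes <- sprintf("n%02d", 1:12)
    prs <- t(combn(nodes, 2))
    have <- paste(edges$node1, edges$node2)
    cand <- prs[!paste(prs[, 1], prs[, 2]) %in% have, , drop = FALSE]
    if (!nrow(cand)) next
    add <- cand[sample.int(nrow(cand), 1), ]
    after <- communityList(findCommunities(
      rbind(edges, data.frame(node1 = add[1], node2 = add[2])), 3))
    for (m in before)
      expect_true(any(vapply(after, function(big) all(m %in% big), NA)))
  }
})

test_that("node relabeling permutes members but not community sizes", {
  set.seed(707)
  edges <- randomEdges(14, 0.35)
  base <- findCommunities(edges, 3)
  perm <- setNames(sample(sprintf("m%02d", 1:14)), sprintf("n%02d", 1:14))
  rel <- data.frame(node1 = unname(perm[edges$node1]),
                    node2 = unname(perm[edges$node2]))
  got <- findCommunities(rel, 3)
  expect_equal(sort(lengths(communityList(base))),
               sort(lengths(communityList(got))))
})

test_that("membership table covers every node once, multi-membership joined", {
  overlap <- edgeDf("a", "b", "b", "c", "a", "c",
                    "c", "d", "d", "e", "c", "e")
  comms <- findCommunities(overlap, 3)
  tab <- communityMembershipTable(comms, c("a", "b", "c", "d", "e", "zz"))
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$communities[tab$node == "c"], "C1;C2")
  expect_equal(tab$communities[tab$node == "zz"], "none")
  expect_false(anyDuplicated(tab$node) > 0)
})
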