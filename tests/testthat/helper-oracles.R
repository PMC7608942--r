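# Independent brute-force oracles used to validate the DP chaining and
# the clique-percolation implementation.  Deliberately naive and free of
# igraph so they share no code path with the implementation.

# Maximum chain score over ALL monotone anchor subsequences (both
# orientations), respecting max_gaps; exhaustive recursion, feasible for
# small anchor sets (<= 12 anchors).
chainOracleScore <- function(anchors, params) {
  ms <- params@match_score; gp <- params@gap_penalty; mg <- params@max_gaps
  i <- anchors$i; j <- anchors$j
  n <- length(i)
  best <- -Inf
  for (orient in c(1L, -1L)) {
    extend <- function(last, score) {
      best <<- max(best, score)
      for (t in seq_len(n)) {
        di <- i[t] - i[last] - 1L
        dj <- orient * (j[t] - j[last]) - 1L
        if (di >= 0L && dj >= 0L && di <= mg && dj <= mg)
          extend(t, score + ms + gp * (di + dj))
      }
    }
    for (s in seq_len(n)) extend(s, ms)
  }
  best
}

# Clique percolation by explicit enumeration: all k-subsets that are
# cliques, pairwise adjacency when sharing exactly k-1 nodes, connected
# components by hand-rolled BFS.  Returns a canonical list of sorted
# member vectors ordered for set comparison.
cpmOracle <- function(edges, k) {
  nodes <- sort(unique(c(edges$node1, edges$node2)))
  ekey <- unique(paste(pmin(edges$node1, edges$node2),
                       pmax(edges$node1, edges$node2), sep = "\r"))
  isEdge <- function(a, b) paste(min(a, b), max(a, b), sep = "\r") %in% ekey
  if (length(nodes) < k) return(list())
  subsets <- combn(nodes, k, simplify = FALSE)
  cliques <- Filter(function(s) {
    prs <- combn(s, 2, simplify = FALSE)
    all(vapply(prs, function(p) isEdge(p[1], p[2]), NA))
  }, subsets)
  if (!length(cliques)) return(list())
  nC <- length(cliques)
  adj <- lapply(seq_len(nC), function(a)
    which(vapply(seq_len(nC), function(b)
      a != b && length(intersect(cliques[[a]], cliques[[b]])) == k - 1, NA)))
  seen <- rep(FALSE, nC)
  comms <- list()
  for (s in seq_len(nC)) {
    if (seen[s]) next
    queue <- s; comp <- integer(0)
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (seen[x]) next
      seen[x] <- TRUE
      comp <- c(comp, x)
      queue <- c(queue, adj[[x]])
    }
    comms[[length(comms) + 1]] <- sort(unique(unlist(cliques[comp])))
  }
  canonCommunities(comms)
}

# canonical form for comparing community collections as sets of sets
canonCommunities <- function(x) {
  x <- lapply(x, sort)
  x[order(vapply(x, paste, "", collapse = "\r"))]
}

randomEdges <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  prs <- combn(nodes, 2)
  keep <- runif(ncol(prs)) < p
  data.frame(node1 = prs[1, keep], node2 = prs[2, keep],
             stringsAsFactors = FALSE)
}

randomAnchors <- function(n, L = 15L) {
  cells <- expand.grid(i = seq_len(L), j = seq_len(L))
  pick <- cells[sample.int(nrow(cells), n), ]
  data.frame(gene_a = sprintf("a%d", seq_len(n)),
             gene_b = sprintf("b%d", seq_len(n)),
             i = pick$i, j = pick$j, stringsAsFactors = FALSE)
}

senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

randomCdsSeq <- function(n_codons) {
  paste(sample(senseCodons(), n_codons, replace = TRUE), collapse = "")
}
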