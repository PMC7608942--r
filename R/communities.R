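#' @include AllClasses.R network.R
NULL

#' Overlapping community detection by k-clique percolation
#'
#' Enumerates all k-cliques of the (simple, undirected) graph; two
#' k-cliques are adjacent iff they share exactly k-1 nodes; communities
#' are the node-set unions of the connected components of this clique
#' adjacency graph.  Communities may overlap.  Output is deterministic:
#' ordered by decreasing size, ties by lexicographically smallest
#' member, ids `"C1"`, `"C2"`, ... assigned in that order.
#'
#' @param network A [SyntenyNetwork-class], an igraph object, or an
#'   edge data.frame with columns `node1`, `node2`.
#' @param k Clique size, at least 2 (default 3, the standard setting
#'   for syntenic community detection).
#' @return A [CommunitySet-class].
#' @examples
#' edges <- data.frame(node1 = c("a", "b", "a", "c", "c", "d"),
#'                     node2 = c("b", "c", "c", "d", "e", "e"))
#' communityList(findCommunities(edges, k = 3))
#' @export
findCommunities <- function(network, k = 3L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  g <- if (is(network, "SyntenyNetwork")) {
    asIgraph(network)
  } else if (inherits(network, "igraph")) {
    network
  } else {
    igraph::graph_from_data_frame(network[, c("node1", "node2")],
                                  directed = FALSE)
  }
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0)
    return(new("CommunitySet", communities = list(), k = k))
  cl <- igraph::cliques(g, min = k, max = k)
  if (!length(cl))
    return(new("CommunitySet", communities = list(), k = k))
  members <- lapply(cl, function(x) sort(names(x)))
  # cliques sharing a (k-1)-subset share exactly k-1 nodes; use the
  # subsets as join keys and merge with union-find
  parent <- seq_along(members)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keymap <- new.env(parent = emptyenv(), hash = TRUE)
  for (ci in seq_along(members)) {
    mem <- members[[ci]]
    for (drop in seq_len(k)) {
      key <- paste(mem[-drop], collapse = "\r")
      prev <- keymap[[key]]
      if (is.null(prev)) {
        keymap[[key]] <- ci
      } else {
        ra <- find(prev); rb <- find(ci)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(members), find, 0L)
  comms <- lapply(split(seq_along(members), roots), function(idx)
    sort(unique(unlist(members[idx]))))
  ord <- order(-lengths(comms), vapply(comms, `[[`, "", 1L))
  comms <- unname(comms[ord])
  names(comms) <- paste0("C", seq_along(comms))
  new("CommunitySet", communities = comms, k = k)
}

#' Per-gene community membership table
#'
#' Every family node appears exactly once; multiple memberships are
#' `;`-joined in community-id order and unclustered genes are reported
#' as `"none"`.
#'
#' @param communities A [CommunitySet-class].
#' @param nodes Character vector of family gene ids, or a
#'   [SyntenyNetwork-class] whose nodes are used.
#' @return data.frame with columns `node`, `communities`.
#' @export
communityMembershipTable <- function(communities, nodes) {
  if (is(nodes, "SyntenyNetwork")) nodes <- networkNodes(nodes)$node
  nodes <- sort(unique(nodes))
  cl <- communityList(communities)
  membership <- vapply(nodes, function(n) {
    inx <- names(cl)[vapply(cl, function(m) n %in% m, NA)]
    if (length(inx)) paste(inx, collapse = ";") else "none"
  }, "")
  data.frame(node = nodes, communities = unname(membership),
             stringsAsFactors = FALSE)
}

#' Write communities and membership tables
#'
#' @param communities A [CommunitySet-class].
#' @param nodes Family gene ids (see [communityMembershipTable()]).
#' @param communitiesPath,membershipPath Output TSV files.
#' @return `communitiesPath`, invisibly.
#' @export
writeCommunities <- function(communities, nodes, communitiesPath,
                             membershipPath) {
  cl <- communityList(communities)
  writeTsv(data.frame(
    community_id = names(cl), size = lengths(cl),
    members = vapply(cl, paste, "", collapse = ";"),
    stringsAsFactors = FALSE), communitiesPath)
  writeTsv(communityMembershipTable(communities, nodes), membershipPath)
  invisible(communitiesPath)
}
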