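#' @include AllClasses.R
NULL

#' Assemble the global synteny network from collinear blocks
#'
#' Every anchor pair of every block becomes one undirected edge; a pair
#' anchored in several blocks yields a single edge annotated with all
#' supporting block ids.  Node species are inferred from the gene table.
#'
#' @param x A [CollinearBlockSet-class] (or the list returned by
#'   [runAllPairs()]).
#' @param genes A [GeneTable-class]; an anchor gene absent from it is an
#'   error.
#' @return A [SyntenyNetwork-class] whose nodes are the genes incident
#'   to at least one edge.
#' @export
buildNetwork <- function(x, genes) {
  if (is.list(x) && !is(x, "CollinearBlockSet")) x <- x$blocks
  a <- blockAnchors(x)
  g <- geneRecords(genes)
  if (nrow(a) == 0)
    return(new("SyntenyNetwork",
               nodes = data.frame(node = character(0),
                                  species = character(0)),
               edges = data.frame(node1 = character(0),
                                  node2 = character(0),
                                  block_ids = character(0))))
  if (!all(c(a$gene_a, a$gene_b) %in% g$gene_id))
    stop("anchor gene(s) absent from gene table: ",
         paste(head(setdiff(c(a$gene_a, a$gene_b), g$gene_id), 5),
               collapse = ", "))
  cp <- .canonPair(a$gene_a, a$gene_b)
  key <- paste(cp$a, cp$b, sep = "\r")
  support <- tapply(a$block_id, key,
                    function(b) paste(sort(unique(b)), collapse = ";"))
  uq <- !duplicated(key)
  edges <- data.frame(node1 = cp$a[uq], node2 = cp$b[uq],
                      block_ids = as.character(support[key[uq]]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$node1, edges$node2)))
  nodes <- data.frame(node = ids,
                      species = g$species[match(ids, g$gene_id)],
                      stringsAsFactors = FALSE)
  new("SyntenyNetwork", nodes = nodes, edges = edges)
}

#' Extract a gene family's subnetwork
#'
#' Induced subgraph on the family's genes: an edge survives only when
#' both endpoints are family members.  Family members without any
#' syntenic partner are retained as degree-0 nodes so that unclustered
#' genes stay visible downstream.
#'
#' @param network A [SyntenyNetwork-class].
#' @param familyIds Non-empty character vector of family gene ids.
#' @param genes Optional [GeneTable-class] used to annotate species for
#'   family members absent from the network.
#' @return A [SyntenyNetwork-class]; if no family id occurs in the
#'   network a warning is raised and the result has no edges.
#' @export
extractFamilySubnetwork <- function(network, familyIds, genes = NULL) {
  if (length(familyIds) == 0) stop("familyIds must be non-empty")
  familyIds <- unique(familyIds)
  e <- networkEdges(network)
  keep <- e$node1 %in% familyIds & e$node2 %in% familyIds
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  if (!any(networkNodes(network)$node %in% familyIds))
    warning("no family gene occurs in the network")
  sp <- networkNodes(network)$species[
    match(familyIds, networkNodes(network)$node)]
  if (!is.null(genes)) {
    g <- geneRecords(genes)
    missing <- is.na(sp)
    sp[missing] <- g$species[match(familyIds[missing], g$gene_id)]
  }
  nodes <- data.frame(node = familyIds, species = sp,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  new("SyntenyNetwork", nodes = nodes, edges = edges)
}

#' Retrieve the full gene content of blocks containing a family
#'
#' Returns every anchor pair of every block in which at least one
#' anchor touches a family gene — the genomic-context content of the
#' family's syntenic blocks.
#'
#' @param x A [CollinearBlockSet-class].
#' @param familyIds Character vector of family gene ids.
#' @return Named list (by `block_id`) of anchor data.frames.
#' @export
blockContext <- function(x, familyIds) {
  a <- blockAnchors(x)
  touched <- unique(a$block_id[a$gene_a %in% familyIds |
                                 a$gene_b %in% familyIds])
  out <- lapply(touched, function(b) {
    rows <- a[a$block_id == b, c("gene_a", "gene_b", "i", "j")]
    rownames(rows) <- NULL
    rows
  })
  names(out) <- touched
  out[order(names(out))]
}

#' Node degrees of a synteny network
#'
#' @param x A [SyntenyNetwork-class].
#' @return Named integer vector over all nodes (degree 0 included).
#' @export
nodeDegrees <- function(x) {
  e <- networkEdges(x)
  n <- networkNodes(x)$node
  deg <- table(factor(c(e$node1, e$node2), levels = n))
  setNames(as.integer(deg), n)
}

#' Write a network as edge-list and node-attribute tables
#'
#' Edge list TSV (`node1`, `node2`, `block_ids`) and node table
#' (`node`, `species`, `degree`), loadable by standard graph viewers.
#'
#' @param x A [SyntenyNetwork-class].
#' @param edgePath,nodePath Output files.
#' @return `edgePath`, invisibly.
#' @export
writeNetwork <- function(x, edgePath, nodePath) {
  writeTsv(networkEdges(x), edgePath)
  deg <- nodeDegrees(x)
  nodes <- networkNodes(x)
  nodes$degree <- as.integer(deg[nodes$node])
  writeTsv(nodes, nodePath)
  invisible(edgePath)
}
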