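#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# GeneTable
# ---------------------------------------------------------------------------

#' GeneTable: per-gene annotation records
#'
#' Holds one record per gene: identifier (`"species|localId"`), species,
#' chromosome, 0-based half-open interval, strand, rank (0-based position
#' among the genes of its chromosome ordered by start, ties by gene id)
#' and optionally the exon count of the representative (longest-CDS)
#' isoform.  Gene rank, not base-pair position, is the coordinate used by
#' the collinearity stage.
#'
#' @slot genes A data.frame with columns `gene_id`, `species`, `chrom`,
#'   `start`, `end`, `strand`, `rank`, `exon_count`.
#' @export
setClass("GeneTable", representation(genes = "data.frame"))

setValidity("GeneTable", function(object) {
  g <- object@genes
  need <- c("gene_id", "species", "chrom", "start", "end", "strand",
            "rank", "exon_count")
  if (!all(need %in% colnames(g)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(g)), collapse = ", ")))
  if (nrow(g) == 0) return(TRUE)
  if (anyDuplicated(g$gene_id))
    return("gene_id values are not unique")
  if (any(g$start >= g$end))
    return("all records must satisfy start < end")
  if (any(g$start < 0))
    return("starts must be non-negative")
  if (!all(g$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  for (key in unique(paste(g$species, g$chrom, sep = "\r"))) {
    r <- sort(g$rank[paste(g$species, g$chrom, sep = "\r") == key])
    if (!identical(as.integer(r), seq_len(length(r)) - 1L))
      return("ranks on a chromosome must be a permutation of 0..m-1")
  }
  TRUE
})

#' Construct a GeneTable, assigning per-chromosome ranks
#'
#' Records are ordered within each (species, chromosome) by start
#' position, ties broken by gene id, and assigned 0-based ranks.
#'
#' @param df A data.frame with at least `gene_id`, `species`, `chrom`,
#'   `start`, `end`, `strand`; `exon_count` optional (`NA` when absent).
#' @return A [GeneTable-class] object.
#' @examples
#' gt <- makeGeneTable(data.frame(
#'   gene_id = c("A|g1", "A|g2"), species = "A", chrom = "chr1",
#'   start = c(10L, 5L), end = c(20L, 9L), strand = "+"))
#' geneRecords(gt)$rank   # g2 precedes g1
#' @export
makeGeneTable <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$exon_count)) df$exon_count <- rep(NA_integer_, nrow(df))
  if (nrow(df) == 0) {
    df$rank <- integer(0)
    df$exon_count <- integer(0)
    cols <- c("gene_id", "species", "chrom", "start", "end", "strand",
              "rank", "exon_count")
    for (cc in cols) if (is.null(df[[cc]])) df[[cc]] <- character(0)
    return(new("GeneTable", genes = df[, cols, drop = FALSE]))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$exon_count <- as.integer(df$exon_count)
  ord <- order(df$species, df$chrom, df$start, df$gene_id)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$species, df$chrom, sep = "\r")
  df$rank <- as.integer(stats::ave(seq_len(nrow(df)), key,
                                   FUN = seq_along)) - 1L
  rownames(df) <- NULL
  cols <- c("gene_id", "species", "chrom", "start", "end", "strand",
            "rank", "exon_count")
  extra <- setdiff(colnames(df), cols)
  new("GeneTable", genes = df[, c(cols, extra), drop = FALSE])
}

#' Accessors for GeneTable
#'
#' `geneRecords()` returns the underlying data.frame; `geneIds()` the
#' gene identifiers; `speciesNames()` the distinct species labels.
#'
#' @param x A [GeneTable-class].
#' @return A data.frame or character vector.
#' @export
geneRecords <- function(x) {
  stopifnot(is(x, "GeneTable"))
  x@genes
}

#' @rdname geneRecords
#' @export
geneIds <- function(x) geneRecords(x)$gene_id

#' @rdname geneRecords
#' @export
speciesNames <- function(x) unique(geneRecords(x)$species)

#' Combine gene tables from several species
#'
#' @param ... [GeneTable-class] objects (or a single list of them).
#' @return A [GeneTable-class] holding all records; an error is raised if
#'   the inputs share species identifiers.
#' @export
combineGeneTables <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "GeneTable"))
    xs <- xs[[1]]
  sp <- unlist(lapply(xs, speciesNames))
  if (anyDuplicated(sp))
    stop("duplicate species identifiers: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "))
  makeGeneTable(do.call(rbind, lapply(xs, geneRecords)))
}

setMethod("show", "GeneTable", function(object) {
  g <- object@genes
  cat(sprintf("GeneTable: %d genes, %d species, %d chromosomes\n",
              nrow(g), length(unique(g$species)),
              length(unique(paste(g$species, g$chrom)))))
  if (nrow(g) > 0) {
    cat(sprintf("  species: %s\n",
                paste(head(unique(g$species), 8), collapse = ", ")))
    cat(sprintf("  exon counts: %s\n",
                if (all(is.na(g$exon_count))) "absent" else "present"))
  }
})

# ---------------------------------------------------------------------------
# ChainParams
# ---------------------------------------------------------------------------

#' Chaining parameters for collinear block detection
#'
#' Defaults mirror the published defaults of the reference collinearity
#' tool: match score 50, gap penalty -1, at least 5 anchors per block,
#' and at most 25 intervening gene ranks between consecutive anchors.
#'
#' @slot match_score Score contributed by each anchor in a chain.
#' @slot gap_penalty Penalty (non-positive) per skipped gene rank.
#' @slot match_size Minimum number of anchors per emitted block.
#' @slot max_gaps Maximum rank gap between consecutive anchors.
#' @export
setClass("ChainParams",
         representation(match_score = "numeric", gap_penalty = "numeric",
                        match_size = "integer", max_gaps = "integer"))

setValidity("ChainParams", function(object) {
  if (object@match_size < 2L) return("match_size must be >= 2")
  if (object@max_gaps < 0L) return("max_gaps must be >= 0")
  if (object@gap_penalty > 0) return("gap_penalty must be <= 0")
  TRUE
})

#' @param match_score,gap_penalty,match_size,max_gaps See slots.
#' @return `chainParams()` returns a validated [ChainParams-class].
#' @rdname ChainParams-class
#' @export
chainParams <- function(match_score = 50, gap_penalty = -1,
                        match_size = 5L, max_gaps = 25L) {
  new("ChainParams", match_score = as.numeric(match_score),
      gap_penalty = as.numeric(gap_penalty),
      match_size = as.integer(match_size), max_gaps = as.integer(max_gaps))
}

setMethod("show", "ChainParams", function(object) {
  cat(sprintf(
    "ChainParams: match_score=%g gap_penalty=%g match_size=%d max_gaps=%d\n",
    object@match_score, object@gap_penalty, object@match_size,
    object@max_gaps))
})

# ---------------------------------------------------------------------------
# CollinearBlockSet
# ---------------------------------------------------------------------------

#' A set of collinear blocks
#'
#' Each block is an ordered chain of homologous anchor pairs between two
#' chromosomes with a score and an orientation (`forward` anchors have
#' strictly increasing ranks in both genomes, `inverted` blocks decrease
#' in the second genome).
#'
#' @slot blocks data.frame: `block_id`, `species_a`, `chrom_a`,
#'   `species_b`, `chrom_b`, `orientation`, `score`, `n_anchors`.
#' @slot anchors data.frame: `block_id`, `gene_a`, `gene_b`, `i`, `j`
#'   (gene ranks), in chain order.
#' @slot params The [ChainParams-class] used.
#' @export
setClass("CollinearBlockSet",
         representation(blocks = "data.frame", anchors = "data.frame",
                        params = "ChainParams"))

#' @param x A [CollinearBlockSet-class].
#' @return `blocks()` the per-block table; `blockAnchors()` the anchor
#'   table.
#' @rdname CollinearBlockSet-class
#' @export
blocks <- function(x) {
  stopifnot(is(x, "CollinearBlockSet"))
  x@blocks
}

#' @rdname CollinearBlockSet-class
#' @export
blockAnchors <- function(x) {
  stopifnot(is(x, "CollinearBlockSet"))
  x@anchors
}

setMethod("show", "CollinearBlockSet", function(object) {
  cat(sprintf("CollinearBlockSet: %d blocks, %d anchors\n",
              nrow(object@blocks), nrow(object@anchors)))
  if (nrow(object@blocks) > 0)
    cat(sprintf("  orientations: %s\n",
                paste(names(table(object@blocks$orientation)),
                      table(object@blocks$orientation),
                      sep = "=", collapse = ", ")))
})

# ---------------------------------------------------------------------------
# SyntenyNetwork
# ---------------------------------------------------------------------------

#' Microsynteny network
#'
#' An undirected simple graph whose nodes are genes and whose edges are
#' syntenic anchor relationships.  Edges are unweighted; the identifiers
#' of the blocks supporting each edge are kept as an annotation.
#'
#' @slot nodes data.frame: `node`, `species`.
#' @slot edges data.frame: `node1`, `node2` (canonically ordered),
#'   `block_ids` (`;`-joined).
#' @export
setClass("SyntenyNetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("SyntenyNetwork", function(object) {
  e <- object@edges
  if (nrow(e) > 0) {
    if (any(e$node1 == e$node2)) return("self loops are not allowed")
    if (anyDuplicated(paste(e$node1, e$node2, sep = "\r")))
      return("duplicate edges")
    if (!all(c(e$node1, e$node2) %in% object@nodes$node))
      return("edge endpoints missing from node table")
  }
  TRUE
})

#' @param x A [SyntenyNetwork-class].
#' @return `networkNodes()`/`networkEdges()` return the node and edge
#'   tables; `asIgraph()` an [igraph::graph] for interoperability.
#' @rdname SyntenyNetwork-class
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "SyntenyNetwork"))
  x@nodes
}

#' @rdname SyntenyNetwork-class
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "SyntenyNetwork"))
  x@edges
}

#' @rdname SyntenyNetwork-class
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "SyntenyNetwork"))
  igraph::graph_from_data_frame(
    d = x@edges[, c("node1", "node2"), drop = FALSE],
    directed = FALSE, vertices = x@nodes)
}

setMethod("show", "SyntenyNetwork", function(object) {
  cat(sprintf("SyntenyNetwork: %d nodes, %d edges, %d species\n",
              nrow(object@nodes), nrow(object@edges),
              length(unique(object@nodes$species))))
})

# ---------------------------------------------------------------------------
# CommunitySet
# ---------------------------------------------------------------------------

#' Overlapping syntenic communities (k-clique percolation)
#'
#' Communities are node-set unions of connected components of the
#' k-clique adjacency graph (two k-cliques adjacent iff they share
#' exactly k-1 nodes); a node may belong to several communities.
#' Communities are ordered by decreasing size, ties by lexicographically
#' smallest member, and named `"C1"`, `"C2"`, ...
#'
#' @slot communities Named list of sorted member vectors.
#' @slot k Clique size used.
#' @export
setClass("CommunitySet",
         representation(communities = "list", k = "integer"))

setValidity("CommunitySet", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  sizes <- lengths(object@communities)
  if (length(sizes) && any(sizes < object@k))
    return("every community must have at least k members")
  TRUE
})

#' @param x A [CommunitySet-class].
#' @return `communityList()` returns the named list of member vectors;
#'   `cliqueSize()` the k used.
#' @rdname CommunitySet-class
#' @export
communityList <- function(x) {
  stopifnot(is(x, "CommunitySet"))
  x@communities
}

#' @rdname CommunitySet-class
#' @export
cliqueSize <- function(x) {
  stopifnot(is(x, "CommunitySet"))
  x@k
}

setMethod("length", "CommunitySet", function(x) length(x@communities))

setMethod("show", "CommunitySet", function(object) {
  cat(sprintf("CommunitySet: %d communities at k=%d\n",
              length(object@communities), object@k))
  if (length(object@communities))
    cat(sprintf("  sizes: %s\n",
                paste(lengths(object@communities), collapse = ", ")))
})
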