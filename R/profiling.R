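#' @include AllClasses.R communities.R
NULL

.leafOrder <- function(tree) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label
}

#' Phylogenomic synteny profile: community-by-species matrix
#'
#' Rows are community ids plus a `"none"` row for unclustered family
#' genes; columns are species in species-tree leaf order; cells count
#' the family genes of that species in that community.  A gene in
#' several communities is counted in each (overlap is a feature of
#' clique percolation); the `"none"` row prevents silent loss of
#' unclustered genes.  A binary presence/absence variant is returned
#' alongside the counts.
#'
#' @param communities A [CommunitySet-class].
#' @param genes A [GeneTable-class] resolving each gene to a species.
#' @param tree Species tree (`phylo`, newick string, or file path);
#'   every profiled species must map to exactly one leaf.
#' @param familyIds Family gene ids defining the profiled set (default:
#'   all community members, in which case the `"none"` row is empty).
#' @return List with matrices `counts` and `presence`.
#' @export
buildProfile <- function(communities, genes, tree, familyIds = NULL) {
  cl <- communityList(communities)
  if (is.null(familyIds)) familyIds <- unique(unlist(cl))
  g <- geneRecords(genes)
  sp <- g$species[match(familyIds, g$gene_id)]
  if (anyNA(sp))
    stop("family gene(s) absent from gene table: ",
         paste(head(familyIds[is.na(sp)], 5), collapse = ", "))
  leaves <- .leafOrder(tree)
  missing <- setdiff(unique(sp), leaves)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  clustered <- unique(unlist(cl))
  rows <- c(names(cl), "none")
  counts <- matrix(0L, nrow = length(rows), ncol = length(leaves),
                   dimnames = list(rows, leaves))
  for (cid in names(cl)) {
    mem <- intersect(cl[[cid]], familyIds)
    tab <- table(factor(g$species[match(mem, g$gene_id)], levels = leaves))
    counts[cid, ] <- as.integer(tab)
  }
  unclustered <- setdiff(familyIds, clustered)
  counts["none", ] <- as.integer(
    table(factor(g$species[match(unclustered, g$gene_id)],
                 levels = leaves)))
  list(counts = counts, presence = (counts > 0) + 0L)
}

#' Per-species family copy-number table
#'
#' @param genes A [GeneTable-class].
#' @param familyIds Family gene ids.
#' @return data.frame `species`, `copies` (0 allowed and reported for
#'   every species present in the gene table).
#' @export
copyNumberTable <- function(genes, familyIds) {
  g <- geneRecords(genes)
  sps <- sort(unique(g$species))
  fam <- g[g$gene_id %in% familyIds, , drop = FALSE]
  data.frame(species = sps,
             copies = as.integer(table(factor(fam$species, levels = sps))),
             stringsAsFactors = FALSE)
}

#' Exon-count summaries per community
#'
#' For each community (and `"none"` for unclustered family genes):
#' sample size, mean, median, mode (ties resolved to the smallest modal
#' value) and the full exon-count histogram.
#'
#' @param communities A [CommunitySet-class].
#' @param genes A [GeneTable-class] with exon counts (GFF3 input or the
#'   simulator); if every exon count is absent an error advises GFF3
#'   input.
#' @param familyIds Optional family set defining the `"none"` group.
#' @return List with `summary` (data.frame `group`, `n`, `mean`,
#'   `median`, `mode`) and `histograms` (named list of tables).  Empty
#'   groups are excluded with a warning.
#' @export
exonSummary <- function(communities, genes, familyIds = NULL) {
  g <- geneRecords(genes)
  if (all(is.na(g$exon_count)))
    stop("no exon counts available; annotate genes from GFF3 input")
  cl <- communityList(communities)
  groups <- lapply(cl, identity)
  if (!is.null(familyIds))
    groups <- c(groups, list(none = setdiff(familyIds, unique(unlist(cl)))))
  summary <- list(); histograms <- list()
  for (nm in names(groups)) {
    ex <- g$exon_count[match(groups[[nm]], g$gene_id)]
    ex <- ex[!is.na(ex)]
    if (!length(ex)) {
      # an empty "none" pseudo-group just means every gene clustered
      if (nm != "none")
        warning("group ", nm, " has no genes with exon counts; excluded")
      next
    }
    h <- table(ex)
    modal <- as.integer(names(h)[h == max(h)])
    summary[[nm]] <- data.frame(
      group = nm, n = length(ex), mean = mean(ex),
      median = median(ex), mode = min(modal), stringsAsFactors = FALSE)
    histograms[[nm]] <- h
  }
  list(summary = do.call(rbind, c(summary, list(make.row.names = FALSE))),
       histograms = histograms)
}
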