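#' @include simulate.R collinearity.R network.R communities.R profiling.R molevo.R
NULL

#' Run the full microsynteny-network pipeline
#'
#' Stages: collinear block detection over all n(n+1)/2 genome pairs,
#' global network assembly, family subnetwork extraction, k-clique
#' percolation, phylogenomic profiling (when a species tree is given),
#' exon-count summaries (when exon counts are available), tandem
#' flagging, and per-community Ks estimation (when coding sequences are
#' given).  A manifest records the configuration digest, seed and
#' per-stage row counts; a rerun with the same inputs and seed is
#' identical.
#'
#' @param genes A [GeneTable-class] covering all genomes (or a list of
#'   per-species tables).
#' @param hits Homology table; filtered through [filterHomology()] with
#'   `evalueMax`/`maxHits` before use.
#' @param familyIds Non-empty vector of focal-family gene ids (an empty
#'   family list is an error before any computation starts).
#' @param tree Optional species tree (`phylo`, newick string or path).
#' @param cds,proteins Optional named sequence vectors for Ks.
#' @param params A [ChainParams-class].
#' @param k Clique size for community detection (default 3).
#' @param evalueMax,maxHits Homology filter settings.
#' @param outDir Optional directory; when given, every stage table is
#'   written there.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic; only the simulator consumes randomness).
#' @return List with `blocks`, `manifest`, `network`, `subnetwork`,
#'   `communities`, `membership`, `tandems`, and (when inputs allow)
#'   `profile`, `exons`, `ks`.
#' @export
runPipeline <- function(genes, hits, familyIds, tree = NULL, cds = NULL,
                        proteins = NULL, params = chainParams(), k = 3L,
                        evalueMax = 1e-10, maxHits = 20L, outDir = NULL,
                        seed = NULL) {
  if (length(familyIds) == 0) stop("family gene list is empty")
  if (is.list(genes) && !is(genes, "GeneTable"))
    genes <- combineGeneTables(genes)
  missing_fam <- setdiff(familyIds, geneIds(genes))
  if (length(missing_fam))
    stop("family gene(s) absent from gene table: ",
         paste(head(missing_fam, 5), collapse = ", "))
  hits <- filterHomology(hits, evalueMax = evalueMax, maxHits = maxHits,
                         genes = genes)
  cl <- runAllPairs(genes, hits, params)
  validateBlocks(cl$blocks)
  net <- buildNetwork(cl$blocks, genes)
  sub <- extractFamilySubnetwork(net, familyIds, genes)
  comms <- findCommunities(sub, k = k)
  membership <- communityMembershipTable(comms, sub)
  tandems <- detectTandems(genes, hits)
  out <- list(blocks = cl$blocks, manifest = cl$manifest, network = net,
              subnetwork = sub, communities = comms,
              membership = membership, tandems = tandems)
  if (!is.null(tree))
    out$profile <- buildProfile(comms, genes, tree, familyIds = familyIds)
  if (!all(is.na(geneRecords(genes)$exon_count)))
    out$exons <- exonSummary(comms, genes, familyIds = familyIds)
  if (!is.null(cds) && length(comms) > 0)
    out$ks <- groupKs(communityList(comms), cds, proteins)
  counts <- c(genes = nrow(geneRecords(genes)), hits = nrow(hits),
              blocks = nrow(blocks(cl$blocks)),
              edges = nrow(networkEdges(net)),
              family_nodes = nrow(networkNodes(sub)),
              communities = length(comms))
  out$run <- data.frame(stage = names(counts),
                        rows = as.integer(counts),
                        stringsAsFactors = FALSE)
  out$config <- list(params = params, k = k, evalueMax = evalueMax,
                     maxHits = maxHits, seed = seed)
  if (!is.null(outDir)) .writePipeline(out, genes, outDir)
  out
}

.writePipeline <- function(out, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCollinearity(out$blocks, file.path(dir, "blocks.collinearity"))
  writeTsv(out$manifest, file.path(dir, "manifest.tsv"))
  writeNetwork(out$network, file.path(dir, "network_edges.tsv"),
               file.path(dir, "network_nodes.tsv"))
  writeNetwork(out$subnetwork, file.path(dir, "family_edges.tsv"),
               file.path(dir, "family_nodes.tsv"))
  writeCommunities(out$communities, out$subnetwork,
                   file.path(dir, "communities.tsv"),
                   file.path(dir, "membership.tsv"))
  if (!is.null(out$profile)) {
    writeTsv(cbind(data.frame(community = rownames(out$profile$counts)),
                   as.data.frame(out$profile$counts)),
             file.path(dir, "profile_counts.tsv"))
    writeTsv(cbind(data.frame(community = rownames(out$profile$presence)),
                   as.data.frame(out$profile$presence)),
             file.path(dir, "profile_presence.tsv"))
  }
  if (!is.null(out$exons) && !is.null(out$exons$summary))
    writeTsv(out$exons$summary, file.path(dir, "exon_summary.tsv"))
  if (!is.null(out$ks)) {
    if (!is.null(out$ks$pairs))
      writeTsv(out$ks$pairs, file.path(dir, "ks_pairs.tsv"))
    if (!is.null(out$ks$summary))
      writeTsv(out$ks$summary, file.path(dir, "ks_summary.tsv"))
  }
  writeTsv(out$run, file.path(dir, "stage_counts.tsv"))
  invisible(dir)
}

#' Simulate a dataset and run the pipeline on it
#'
#' Convenience wrapper used by the scenario analyses: simulates under
#' `config`, then runs [runPipeline()] on the simulated gene table,
#' homology hits and focal family, with the species tree taken from the
#' configuration.
#'
#' @param config A [SimConfig-class].
#' @param withKs Compute per-community Ks (default TRUE).
#' @param ... Passed on to [runPipeline()].
#' @return List with `sim` (the [SimulatedDataset-class]) and all
#'   [runPipeline()] outputs.
#' @export
runSimulatedPipeline <- function(config, withKs = TRUE, ...) {
  sim <- simulateDataset(config)
  fam <- familyMembers(sim)
  res <- runPipeline(sim@genes, sim@hits, fam, tree = config@tree,
                     cds = if (withKs) sim@cds else NULL,
                     proteins = if (withKs) sim@proteins else NULL,
                     seed = config@seed, ...)
  c(list(sim = sim), res)
}
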