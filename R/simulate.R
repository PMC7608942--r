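#' @include AllClasses.R io.R molevo.R
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Describes a genome-evolution scenario: an ancestral genome evolves
#' along a species tree under per-branch stochastic events (gene loss,
#' tandem duplication, DNA/RNA transposition, inversion), configured
#' whole-genome duplications/triplications with fractionation, and
#' optional forced single-gene events (used by scenario presets to place
#' one historical duplication-transposition on a named branch).  Coding
#' sequences accumulate synonymous substitutions at `ks_rate` expected
#' synonymous substitutions per synonymous site per unit branch length;
#' transposed copies evolve at `relaxed_multiplier` times that rate,
#' modelling reduced constraint on a duplicate in a new genomic context.
#'
#' @slot tree Species tree (`phylo`) with branch lengths in time units.
#' @slot n_chromosomes,genes_per_chromosome Ancestral genome dimensions.
#' @slot loss_rate,tandem_rate,transposition_rate,inversion_rate Event
#'   rates per gene per unit time.
#' @slot rna_fraction Probability that a stochastic transposition is
#'   RNA-mediated (the copy becomes intronless, exon count 1).
#' @slot wgd_events List of `list(branch, multiplicity, retention_prob)`;
#'   multiplicity 2 (WGD) or 3 (WGT); each duplicate gene is retained
#'   with `retention_prob` (fractionation).  `branch = "root"` applies
#'   the event to the ancestral genome.
#' @slot forced_events List of `list(branch, type, family)` with type
#'   `"rna_transposition"`, `"dna_transposition"` or `"tandem"`.
#' @slot family_of_interest Family label of the focal gene family.
#' @slot ks_rate Expected synonymous substitutions per synonymous site
#'   per unit time.
#' @slot relaxed_multiplier Rate factor (>= 1) for transposed copies.
#' @slot cds_codons Codons per ancestral gene (default 300).
#' @slot exons_root Ancestral exon count per gene (default 9).
#' @slot protect_focal Exempt the focal family from stochastic loss,
#'   transposition and tandem duplication, so that the focal family's
#'   copy-number history is exactly the one scripted by `forced_events`
#'   (an essential gene under strong purifying selection).  Default
#'   TRUE.
#' @slot seed Integer seed; the full output is deterministic given it.
#' @export
setClass("SimConfig", representation(
  tree = "ANY", n_chromosomes = "integer", genes_per_chromosome = "integer",
  loss_rate = "numeric", tandem_rate = "numeric",
  transposition_rate = "numeric", inversion_rate = "numeric",
  rna_fraction = "numeric", wgd_events = "list", forced_events = "list",
  family_of_interest = "character", ks_rate = "numeric",
  relaxed_multiplier = "numeric", cds_codons = "integer",
  exons_root = "integer", protect_focal = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  rates <- c(object@loss_rate, object@tandem_rate,
             object@transposition_rate, object@inversion_rate,
             object@ks_rate)
  if (any(rates < 0)) return("rates must be >= 0")
  if (object@rna_fraction < 0 || object@rna_fraction > 1)
    return("rna_fraction must be in [0, 1]")
  if (object@relaxed_multiplier < 1)
    return("relaxed_multiplier must be >= 1")
  for (ev in object@wgd_events) {
    if (!ev$multiplicity %in% c(2, 3))
      return("WGD multiplicity must be 2 or 3")
    if (ev$retention_prob <= 0 || ev$retention_prob > 1)
      return("retention_prob must be in (0, 1]")
  }
  if (anyDuplicated(object@tree$tip.label))
    return("tree leaf names must be unique")
  TRUE
})

#' @param tree `phylo`, newick string or file path.
#' @param n_chromosomes,genes_per_chromosome,loss_rate,tandem_rate,transposition_rate,inversion_rate,rna_fraction,wgd_events,forced_events,family_of_interest,ks_rate,relaxed_multiplier,cds_codons,exons_root,protect_focal,seed
#'   See the class slots.
#' @return `simConfig()` returns a validated [SimConfig-class].
#' @rdname SimConfig-class
#' @export
simConfig <- function(tree, n_chromosomes = 1L, genes_per_chromosome = 40L,
                      loss_rate = 0, tandem_rate = 0,
                      transposition_rate = 0, inversion_rate = 0,
                      rna_fraction = 0.5, wgd_events = list(),
                      forced_events = list(),
                      family_of_interest = "fam1", ks_rate = 0.1,
                      relaxed_multiplier = 1, cds_codons = 300L,
                      exons_root = 9L, protect_focal = TRUE, seed = 1L) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  new("SimConfig", tree = tree,
      n_chromosomes = as.integer(n_chromosomes),
      genes_per_chromosome = as.integer(genes_per_chromosome),
      loss_rate = loss_rate, tandem_rate = tandem_rate,
      transposition_rate = transposition_rate,
      inversion_rate = inversion_rate, rna_fraction = rna_fraction,
      wgd_events = wgd_events, forced_events = forced_events,
      family_of_interest = family_of_interest, ks_rate = ks_rate,
      relaxed_multiplier = relaxed_multiplier,
      cds_codons = as.integer(cds_codons),
      exons_root = as.integer(exons_root),
      protect_focal = protect_focal, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d species, %d x %d ancestral genes, seed %d\n",
    length(object@tree$tip.label), object@n_chromosomes,
    object@genes_per_chromosome, object@seed))
  cat(sprintf("  rates: loss=%g tandem=%g transposition=%g inversion=%g\n",
              object@loss_rate, object@tandem_rate,
              object@transposition_rate, object@inversion_rate))
  cat(sprintf("  ks_rate=%g relaxed_multiplier=%g; %d WGD, %d forced\n",
              object@ks_rate, object@relaxed_multiplier,
              length(object@wgd_events), length(object@forced_events)))
})

#' Simulated dataset with ground truth
#'
#' @slot genes Combined [GeneTable-class] over all species.
#' @slot cds,proteins Named character vectors keyed by gene id.
#' @slot hits Homology table (within-family pairs, bitscore decreasing
#'   with true distance).
#' @slot truth List of data.frames: `families`, `contexts`, `parents`,
#'   `distances`, `events`.
#' @slot config The [SimConfig-class] used.
#' @export
setClass("SimulatedDataset", representation(
  genes = "GeneTable", cds = "character", proteins = "character",
  hits = "data.frame", truth = "list", config = "SimConfig"))

setMethod("show", "SimulatedDataset", function(object) {
  g <- geneRecords(object@genes)
  cat(sprintf(
    "SimulatedDataset: %d genes in %d species; %d homology pairs\n",
    nrow(g), length(unique(g$species)), nrow(object@hits)))
  foc <- object@config@family_of_interest
  n_f <- sum(object@truth$families$family == foc)
  cat(sprintf("  focal family %s: %d genes\n", foc, n_f))
})

# ---------------------------------------------------------------------------
# simulation state and genome representation
# ---------------------------------------------------------------------------

# The working genome is a plain data.frame, one row per gene in
# chromosomal order (row order within a chromosome IS the gene order):
# id, chrom (integer), family, context, exon, strand, cds, ks_acc
# (accumulated expected synonymous distance), mult (rate multiplier),
# node (genealogy node id).

.newSimState <- function() {
  st <- new.env(parent = emptyenv())
  st$gene_counter <- 0L
  st$ctx_counter <- 0L
  st$par <- integer(0)    # genealogy: parent node per node
  st$ksb <- numeric(0)    # ks at node birth
  st$parents <- list()    # duplication records: copy id -> donor id
  st$events <- list()
  st
}

.newGeneId <- function(state) {
  state$gene_counter <- state$gene_counter + 1L
  paste0("g", state$gene_counter)
}

.newNode <- function(state, parent, ks) {
  state$par <- c(state$par, as.integer(parent))
  state$ksb <- c(state$ksb, ks)
  length(state$par)
}

.logEvent <- function(state, branch, type, genes) {
  state$events[[length(state$events) + 1L]] <-
    data.frame(branch = branch, type = type,
               genes = paste(genes, collapse = ";"),
               stringsAsFactors = FALSE)
}

.randomCds <- function(n_codons) {
  paste(sample(.SENSE, n_codons, replace = TRUE), collapse = "")
}

#' Build the ancestral (root) genome of a simulation
#'
#' Each ancestral gene founds its own family (`"fam<i>"`) and genomic
#' context (`"ctx<i>"`); coding sequences are random sense codons.
#'
#' @param config A [SimConfig-class].
#' @param state Internal simulation state (created when `NULL`).
#' @return The working genome data.frame (see source for the schema).
#' @export
rootGenome <- function(config, state = NULL) {
  if (is.null(state)) state <- .newSimState()
  set.seed(.deriveSeed(config@seed, "root"))
  n <- config@n_chromosomes * config@genes_per_chromosome
  ids <- vapply(seq_len(n), function(i) .newGeneId(state), "")
  nodes <- vapply(seq_len(n), function(i) .newNode(state, 0L, 0), 0L)
  data.frame(
    id = ids,
    chrom = rep(seq_len(config@n_chromosomes),
                each = config@genes_per_chromosome),
    family = paste0("fam", seq_len(n)),
    context = paste0("ctx", seq_len(n)),
    exon = config@exons_root,
    strand = "+",
    cds = vapply(seq_len(n), function(i) .randomCds(config@cds_codons), ""),
    ks_acc = 0, mult = 1, node = nodes,
    stringsAsFactors = FALSE)
}

# insert rows of `piece` after row `at` (0 = prepend)
.insertRows <- function(df, piece, at) {
  if (at == 0) rbind(piece, df)
  else if (at >= nrow(df)) rbind(df, piece)
  else rbind(df[seq_len(at), , drop = FALSE], piece,
             df[(at + 1):nrow(df), , drop = FALSE])
}

#' Apply one evolutionary event to a working genome
#'
#' Event mechanics: `loss` removes a gene and closes ranks; `tandem`
#' inserts a copy immediately after its parent on the same chromosome;
#' `transposition` inserts a copy at a uniformly chosen position on a
#' uniformly chosen chromosome with a fresh context label (RNA-mediated
#' copies additionally become single-exon); `inversion` reverses gene
#' order and flips strands over a contiguous window; `wgd` duplicates
#' every chromosome (`multiplicity` 2 or 3) and then deletes each
#' duplicate gene independently with probability `1 - retention_prob`.
#'
#' Uses the current RNG stream for any unspecified choice.
#'
#' @param genome Working genome data.frame (see [rootGenome()]).
#' @param type One of `"loss"`, `"tandem"`, `"transposition"`,
#'   `"inversion"`, `"wgd"`.
#' @param target Gene id (for loss/tandem/transposition); uniform random
#'   when `NULL`.
#' @param rna For transpositions: RNA-mediated (copy exon count 1).
#' @param relaxed_multiplier Rate factor applied to transposed copies.
#' @param chrom,window For inversions: chromosome and 1-based position
#'   window `c(lo, hi)` within it; a window outside the chromosome is an
#'   error.
#' @param multiplicity,retention_prob For WGD events.
#' @param state Internal simulation state (created when `NULL`).
#' @param branch Branch label recorded in the event log.
#' @return The modified genome data.frame.
#' @export
applyEvent <- function(genome, type, target = NULL, rna = FALSE,
                       relaxed_multiplier = 1, chrom = NULL, window = NULL,
                       multiplicity = 2, retention_prob = 1,
                       state = NULL, branch = "?") {
  if (is.null(state)) {
    state <- .newSimState()
    state$gene_counter <- max(c(0L, suppressWarnings(
      as.integer(sub("^g", "", genome$id[grepl("^g[0-9]+$", genome$id)])))))
    state$par <- rep(0L, max(c(0L, genome$node)))
    state$ksb <- rep(0, max(c(0L, genome$node)))
  }
  pickRow <- function() {
    if (!is.null(target)) {
      r <- which(genome$id == target)
      if (!length(r)) stop("target gene ", target, " not in genome")
      r
    } else sample.int(nrow(genome), 1L)
  }
  if (type == "loss") {
    r <- pickRow()
    .logEvent(state, branch, "loss", genome$id[r])
    genome <- genome[-r, , drop = FALSE]
  } else if (type == "tandem") {
    r <- pickRow()
    copy <- genome[r, , drop = FALSE]
    copy$id <- .newGeneId(state)
    copy$node <- .newNode(state, genome$node[r], genome$ks_acc[r])
    state$parents[[copy$id]] <- genome$id[r]
    .logEvent(state, branch, "tandem", c(genome$id[r], copy$id))
    genome <- .insertRows(genome, copy, r)
  } else if (type == "transposition") {
    r <- pickRow()
    copy <- genome[r, , drop = FALSE]
    copy$id <- .newGeneId(state)
    copy$node <- .newNode(state, genome$node[r], genome$ks_acc[r])
    state$ctx_counter <- state$ctx_counter + 1L
    copy$context <- paste0("ctxT", state$ctx_counter)
    copy$mult <- copy$mult * relaxed_multiplier
    if (rna) copy$exon <- 1L
    state$parents[[copy$id]] <- genome$id[r]
    .logEvent(state, branch,
              if (rna) "rna_transposition" else "dna_transposition",
              c(genome$id[r], copy$id))
    chroms <- unique(genome$chrom)
    # a transposition relocates the copy into a NEW genomic context:
    # the insertion neighborhood must share no gene family with the
    # donor's neighborhood (which, after WGD/WGT, also rules out the
    # homeologous copies of the donor region).  Resample until no
    # family is shared within a 30-rank window; an explicitly given
    # destination chromosome is respected as-is.
    donor_chrom <- genome$chrom[r]
    donor_pos <- sum(genome$chrom[seq_len(r)] == donor_chrom)
    chrom_pos <- stats::ave(seq_len(nrow(genome)), genome$chrom,
                            FUN = seq_along)
    donor_fams <- genome$family[genome$chrom == donor_chrom &
                                  abs(chrom_pos - donor_pos) <= 30]
    for (try in 1:200) {
      dchrom <- if (!is.null(chrom)) chrom else
        chroms[sample.int(length(chroms), 1L)]
      on_chrom <- which(genome$chrom == dchrom)
      pos <- if (length(on_chrom))
        sample.int(length(on_chrom) + 1L, 1L) - 1L else 0L
      if (!is.null(chrom)) break
      near <- on_chrom[abs(seq_along(on_chrom) - pos) <= 30L]
      if (!length(intersect(genome$family[near], donor_fams))) break
    }
    copy$chrom <- dchrom
    if (length(on_chrom)) {
      at <- if (pos == 0) min(on_chrom) - 1L else on_chrom[pos]
      genome <- .insertRows(genome, copy, at)
    } else {
      genome <- rbind(genome, copy)
      genome <- genome[order(genome$chrom), , drop = FALSE]
    }
  } else if (type == "inversion") {
    chroms <- unique(genome$chrom)
    ichrom <- if (!is.null(chrom)) chrom else
      chroms[sample.int(length(chroms), 1L)]
    on_chrom <- which(genome$chrom == ichrom)
    m <- length(on_chrom)
    if (is.null(window)) {
      # small local inversions dominate: window length 1 + Geometric,
      # mean ~5 genes, capped at the chromosome end
      lo <- sample.int(m, 1L)
      len <- 1L + stats::rgeom(1L, 1 / 5)
      window <- c(lo, min(m, lo + len))
    }
    if (window[1] < 1 || window[2] > m || window[1] > window[2])
      stop("inversion window outside chromosome")
    seg <- on_chrom[window[1]:window[2]]
    inv <- genome[rev(seg), , drop = FALSE]
    inv$strand <- ifelse(inv$strand == "+", "-", "+")
    genome[seg, ] <- inv
    .logEvent(state, branch, "inversion", genome$id[seg])
  } else if (type == "wgd") {
    if (!multiplicity %in% c(2, 3)) stop("multiplicity must be 2 or 3")
    orig_chroms <- sort(unique(genome$chrom))
    base <- max(genome$chrom)
    pieces <- list(genome)
    copy_ids <- character(0)
    for (m in seq_len(multiplicity - 1)) {
      dup <- genome
      keep <- rbinom(nrow(dup), 1L, retention_prob) == 1L
      dup <- dup[keep, , drop = FALSE]
      if (!nrow(dup)) next
      dup$chrom <- dup$chrom + m * base
      src_id <- dup$id
      src_node <- dup$node
      dup$id <- vapply(seq_len(nrow(dup)),
                       function(i) .newGeneId(state), "")
      dup$node <- vapply(seq_len(nrow(dup)), function(i)
        .newNode(state, src_node[i], dup$ks_acc[i]), 0L)
      for (i in seq_len(nrow(dup))) state$parents[[dup$id[i]]] <- src_id[i]
      copy_ids <- c(copy_ids, dup$id)
      pieces[[length(pieces) + 1L]] <- dup
    }
    .logEvent(state, branch, sprintf("wgd_x%d", multiplicity), copy_ids)
    genome <- do.call(rbind, pieces)
    genome <- genome[order(genome$chrom), , drop = FALSE]
  } else stop("unknown event type: ", type)
  rownames(genome) <- NULL
  genome
}

#' Evolve a coding sequence by synonymous substitutions
#'
#' Applies `Poisson(distance * S)` substitutions, where `S` is the NG86
#' synonymous site count of the sequence at call time; each substitution
#' is drawn uniformly among all synonymous single-nucleotide changes of
#' the current sequence, so the amino-acid sequence is invariant.
#'
#' @param cds Coding sequence, length divisible by 3, no internal stop.
#' @param distance Expected synonymous substitutions per synonymous
#'   site.
#' @return The evolved coding sequence.
#' @export
evolveCds <- function(cds, distance) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  starts <- seq(1, nchar(cds), 3)
  codons <- substring(cds, starts, starts + 2)
  if (any(.codonTable[codons] == "*")) stop("internal stop codon in CDS")
  if (distance == 0) return(cds)
  k <- vapply(codons, function(cod) {
    o <- .synOptions[[cod]]
    if (is.null(o)) 0L else nrow(o)
  }, 0L, USE.NAMES = FALSE)
  S <- sum(k) / 3
  n_sub <- rpois(1L, distance * S)
  for (s in seq_len(n_sub)) {
    if (sum(k) == 0) break
    ci <- sample.int(length(codons), 1L, prob = k)
    opts <- .synOptions[[codons[ci]]]
    oi <- sample.int(nrow(opts), 1L)
    nts <- strsplit(codons[ci], "")[[1]]
    nts[as.integer(opts[oi, 1])] <- opts[oi, 2]
    codons[ci] <- paste(nts, collapse = "")
    o2 <- .synOptions[[codons[ci]]]
    k[ci] <- if (is.null(o2)) 0L else nrow(o2)
  }
  paste(codons, collapse = "")
}

# ---------------------------------------------------------------------------
# tree traversal
# ---------------------------------------------------------------------------

.nodeLabels <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  inner <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", seq_len(nnode))
  c(tree$tip.label, inner)
}

.processBranch <- function(genome, label, len, config, state) {
  set.seed(.deriveSeed(config@seed, paste0("branch_", label)))
  # speciation: every gene's lineage forks onto this branch
  genome$node <- vapply(seq_len(nrow(genome)), function(i)
    .newNode(state, genome$node[i], genome$ks_acc[i]), 0L)
  genome <- .applyConfiguredEvents(genome, label, config, state)
  # stochastic events
  if (len > 0) {
    n0 <- nrow(genome)
    focal <- config@family_of_interest
    counts <- c(
      loss = rpois(1L, config@loss_rate * len * n0),
      tandem = rpois(1L, config@tandem_rate * len * n0),
      transposition = rpois(1L, config@transposition_rate * len * n0),
      inversion = rpois(1L, config@inversion_rate * len * n0))
    evs <- rep(names(counts), counts)
    if (length(evs) > 1L) evs <- sample(evs)
    for (ev in evs) {
      if (nrow(genome) == 0) break
      eligible <- seq_len(nrow(genome))
      if (config@protect_focal &&
          ev %in% c("loss", "transposition", "tandem"))
        eligible <- which(genome$family != focal)
      if (ev %in% c("loss", "tandem", "transposition") && !length(eligible))
        next
      if (ev == "loss") {
        genome <- applyEvent(genome, "loss",
                             target = genome$id[sample(eligible, 1L)],
                             state = state, branch = label)
      } else if (ev == "tandem") {
        genome <- applyEvent(genome, "tandem",
                             target = genome$id[sample(eligible, 1L)],
                             state = state, branch = label)
      } else if (ev == "transposition") {
        genome <- applyEvent(genome, "transposition",
                             target = genome$id[sample(eligible, 1L)],
                             rna = runif(1) < config@rna_fraction,
                             relaxed_multiplier = config@relaxed_multiplier,
                             state = state, branch = label)
      } else {
        genome <- applyEvent(genome, "inversion", state = state,
                             branch = label)
      }
    }
    # synonymous sequence evolution over the branch
    elapsed <- config@ks_rate * len * genome$mult
    genome$cds <- vapply(seq_len(nrow(genome)), function(i)
      evolveCds(genome$cds[i], elapsed[i]), "")
    genome$ks_acc <- genome$ks_acc + elapsed
  }
  genome
}

.applyConfiguredEvents <- function(genome, label, config, state) {
  for (ev in config@wgd_events) {
    if (identical(ev$branch, label))
      genome <- applyEvent(genome, "wgd", multiplicity = ev$multiplicity,
                           retention_prob = ev$retention_prob,
                           state = state, branch = label)
  }
  for (ev in config@forced_events) {
    if (!identical(ev$branch, label)) next
    members <- sort(genome$id[genome$family == ev$family])
    if (!length(members))
      stop("forced event on branch ", label, ": family ", ev$family,
           " has no members")
    target <- members[1L]
    genome <- switch(
      ev$type,
      rna_transposition = applyEvent(
        genome, "transposition", target = target, rna = TRUE,
        relaxed_multiplier = config@relaxed_multiplier,
        state = state, branch = label),
      dna_transposition = applyEvent(
        genome, "transposition", target = target, rna = FALSE,
        relaxed_multiplier = config@relaxed_multiplier,
        state = state, branch = label),
      tandem = applyEvent(genome, "tandem", target = target,
                          state = state, branch = label),
      stop("unknown forced event type: ", ev$type))
  }
  genome
}

# true pairwise synonymous distance from the gene genealogy: walk both
# ancestor chains to the lowest common node; divergence time is the
# earliest exit from it along either path
.pairDistance <- function(state, nodeA, ksA, nodeB, ksB) {
  chain <- function(n) {
    out <- integer(0)
    while (n != 0L) {
      out <- c(out, n)
      n <- state$par[n]
    }
    out
  }
  ca <- chain(nodeA); cb <- chain(nodeB)
  lca <- ca[match(TRUE, ca %in% cb)]
  exits <- numeric(0)
  ia <- match(lca, ca); ib <- match(lca, cb)
  if (ia > 1L) exits <- c(exits, state$ksb[ca[ia - 1L]])
  if (ib > 1L) exits <- c(exits, state$ksb[cb[ib - 1L]])
  t0 <- if (length(exits)) min(exits) else min(ksA, ksB)
  ksA + ksB - 2 * t0
}

# ---------------------------------------------------------------------------
# top-level simulation
# ---------------------------------------------------------------------------

#' Simulate a multi-species gene-order and sequence dataset
#'
#' Evolves the ancestral genome along the configured species tree and
#' assembles pipeline-ready inputs: a combined [GeneTable-class] (gene
#' order, strands, exon counts), CDS and protein sequences, a homology
#' table containing exactly the within-family gene pairs (bitscore a
#' decreasing function of true synonymous distance, e-value a monotone
#' transform of the bitscore), and ground-truth tables (family and
#' context labels, duplication parent map, true pairwise synonymous
#' distances, event log).  Deterministic given `config@seed`.
#'
#' @param config A [SimConfig-class].
#' @return A [SimulatedDataset-class].
#' @export
simulateDataset <- function(config) {
  validObject(config)
  state <- .newSimState()
  root <- rootGenome(config, state)
  tree <- config@tree
  labels <- .nodeLabels(tree)
  ntip <- length(tree$tip.label)
  root_idx <- ntip + 1L
  root_label <- labels[root_idx]
  set.seed(.deriveSeed(config@seed, paste0("branch_", root_label)))
  root <- .applyConfiguredEvents(root, root_label, config, state)
  if (!identical(root_label, "root"))
    root <- .applyConfiguredEvents(root, "root", config, state)

  genomes <- list()
  recurse <- function(node_idx, genome) {
    kids <- which(tree$edge[, 1] == node_idx)
    for (e in kids) {
      child <- tree$edge[e, 2]
      len <- if (!is.null(tree$edge.length)) tree$edge.length[e] else 1
      if (is.na(len)) len <- 0
      g2 <- .processBranch(genome, labels[child], len, config, state)
      if (child <= ntip) {
        genomes[[labels[child]]] <<- g2
      } else {
        recurse(child, g2)
      }
    }
  }
  recurse(root_idx, root)

  # assemble extant gene tables with base-pair coordinates from ranks
  tabs <- list()
  for (sp in names(genomes)) {
    g <- genomes[[sp]]
    g <- g[order(g$chrom), , drop = FALSE]
    r <- as.integer(stats::ave(seq_len(nrow(g)), g$chrom,
                               FUN = seq_along)) - 1L
    len <- nchar(g$cds) + (g$exon - 1L) * 100L
    tabs[[sp]] <- data.frame(
      gene_id = paste0(sp, "|", g$id), species = sp,
      chrom = paste0("chr", g$chrom),
      start = r * 5000L, end = r * 5000L + len,
      strand = g$strand, exon_count = g$exon,
      family = g$family, context = g$context,
      node = g$node, ks_acc = g$ks_acc,
      cds = g$cds, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, tabs)
  rownames(all) <- NULL
  gt <- makeGeneTable(all[, c("gene_id", "species", "chrom", "start",
                              "end", "strand", "exon_count")])
  cds <- setNames(all$cds, all$gene_id)
  proteins <- vapply(cds, translateCds, "")

  # homology = within-family pairs; truth distances alongside
  hits <- list(); dists <- list()
  for (fam in unique(all$family)) {
    rows <- which(all$family == fam)
    if (length(rows) < 2) next
    pr <- combn(rows, 2)
    d <- vapply(seq_len(ncol(pr)), function(c)
      .pairDistance(state, all$node[pr[1, c]], all$ks_acc[pr[1, c]],
                    all$node[pr[2, c]], all$ks_acc[pr[2, c]]), 0)
    bits <- pmax(50, 500 * exp(-d))
    ga <- all$gene_id[pr[1, ]]; gb <- all$gene_id[pr[2, ]]
    cp <- .canonPair(ga, gb)
    hits[[fam]] <- data.frame(query_id = cp$a, subject_id = cp$b,
                              bitscore = round(bits, 1),
                              evalue = 10^(-bits / 4),
                              stringsAsFactors = FALSE)
    dists[[fam]] <- data.frame(gene_a = cp$a, gene_b = cp$b, family = fam,
                               d_true = d, stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, c(hits,
            list(make.row.names = FALSE)))
          else data.frame(query_id = character(0), subject_id = character(0),
                          bitscore = numeric(0), evalue = numeric(0))
  dists <- if (length(dists)) do.call(rbind, c(dists,
             list(make.row.names = FALSE)))
           else data.frame(gene_a = character(0), gene_b = character(0),
                           family = character(0), d_true = numeric(0))
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL

  parents <- if (length(state$parents))
    data.frame(copy = names(state$parents),
               donor = unlist(state$parents, use.names = FALSE),
               stringsAsFactors = FALSE)
    else data.frame(copy = character(0), donor = character(0))
  events <- if (length(state$events))
    do.call(rbind, c(state$events, list(make.row.names = FALSE)))
    else data.frame(branch = character(0), type = character(0),
                    genes = character(0))
  truth <- list(
    families = data.frame(gene_id = all$gene_id, family = all$family,
                          stringsAsFactors = FALSE),
    contexts = data.frame(gene_id = all$gene_id, context = all$context,
                          stringsAsFactors = FALSE),
    parents = parents, distances = dists, events = events)
  new("SimulatedDataset", genes = gt, cds = cds, proteins = proteins,
      hits = hits, truth = truth, config = config)
}

#' Gene ids of the focal family of a simulated dataset
#'
#' @param sim A [SimulatedDataset-class].
#' @param family Family label (default: the configured focal family).
#' @return Character vector of gene ids.
#' @export
familyMembers <- function(sim, family = sim@config@family_of_interest) {
  f <- sim@truth$families
  f$gene_id[f$family == family]
}

#' Write a simulated dataset to pipeline input files
#'
#' Per species: GFF3, BED, CDS FASTA and protein FASTA; plus the
#' homology table (12-column tabular), the species tree (newick) and the
#' ground-truth tables as TSV.
#'
#' @param sim A [SimulatedDataset-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- geneRecords(sim@genes)
  for (sp in unique(g$species)) {
    sub <- makeGeneTable(g[g$species == sp, , drop = FALSE])
    writeGff3(sub, file.path(dir, paste0(sp, ".gff3")), cds = sim@cds)
    writeBed(sub, file.path(dir, paste0(sp, ".bed")))
    ids <- geneIds(sub)
    writeFasta(sim@cds[ids], file.path(dir, paste0(sp, ".cds.fa")))
    writeFasta(sim@proteins[ids], file.path(dir, paste0(sp, ".pep.fa")))
  }
  writeHomologyTable(sim@hits, file.path(dir, "homology.tsv"))
  ape::write.tree(sim@config@tree, file.path(dir, "species.nwk"))
  for (nm in names(sim@truth))
    writeTsv(sim@truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  invisible(dir)
}

# ---------------------------------------------------------------------------
# planted-anchor chromosome pairs
# ---------------------------------------------------------------------------

#' Simulate a chromosome pair with planted collinear blocks and noise
#'
#' Plants non-overlapping collinear runs (forward or inverted diagonals)
#' of `block_sizes` anchors on an `L` x `L` rank grid, then adds
#' spurious anchors uniformly at `noise_frac` of the planted anchor
#' count.  Noise anchors are rejected when they fall inside a planted
#' block's bounding box or within the chainable extension cone
#' (`max_gaps + 1` ranks, monotone quadrants) of any existing anchor, so
#' the planted blocks remain the unambiguous ground truth.
#'
#' @param block_sizes Integer vector: anchors per planted block.
#' @param L Ranks per chromosome (default 1000).
#' @param noise_frac Spurious anchors as a fraction of planted anchors.
#' @param max_gaps Gap bound the noise must respect (default 25).
#' @return List with `anchors` (data.frame `gene_a`, `gene_b`, `i`, `j`
#'   in shuffled order) and `truth` (logical vector: planted anchor?).
#' @export
simulatePlantedAnchors <- function(block_sizes, L = 1000L,
                                   noise_frac = 0.05, max_gaps = 25L) {
  rows <- list()
  span <- ceiling(L / (length(block_sizes) + 1L))
  for (b in seq_along(block_sizes)) {
    m <- block_sizes[b]
    i0 <- (b - 1L) * span + sample.int(max(1L, span - m - 1L), 1L)
    j0 <- (b - 1L) * span + sample.int(max(1L, span - m - 1L), 1L)
    inverted <- runif(1) < 0.5
    i <- i0 + seq_len(m) - 1L
    j <- if (inverted) j0 + m - seq_len(m) else j0 + seq_len(m) - 1L
    rows[[b]] <- data.frame(
      gene_a = sprintf("pA_%d_%d", b, seq_len(m)),
      gene_b = sprintf("pB_%d_%d", b, seq_len(m)),
      i = i, j = j, planted = TRUE, stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, rows)
  n_noise <- round(noise_frac * nrow(planted))
  cone <- max_gaps + 1L
  noise <- list(); tries <- 0L
  all_i <- planted$i; all_j <- planted$j
  while (length(noise) < n_noise && tries < 10000L) {
    tries <- tries + 1L
    ni <- sample.int(L, 1L); nj <- sample.int(L, 1L)
    di <- ni - all_i; dj <- nj - all_j
    chainable <- (abs(di) <= cone & abs(dj) <= cone)
    if (any(chainable)) next
    noise[[length(noise) + 1L]] <- data.frame(
      gene_a = sprintf("nA_%d", length(noise) + 1L),
      gene_b = sprintf("nB_%d", length(noise) + 1L),
      i = ni, j = nj, planted = FALSE, stringsAsFactors = FALSE)
    all_i <- c(all_i, ni); all_j <- c(all_j, nj)
  }
  anc <- rbind(planted, if (length(noise)) do.call(rbind, noise))
  ord <- sample.int(nrow(anc))
  anc <- anc[ord, , drop = FALSE]
  rownames(anc) <- NULL
  list(anchors = anc[, c("gene_a", "gene_b", "i", "j")],
       truth = anc$planted)
}

# ---------------------------------------------------------------------------
# scenario presets
# ---------------------------------------------------------------------------

#' Mammal-style scenario: stem duplication with RNA transposition
#'
#' Six ingroup species plus one outgroup; on the ingroup stem the focal
#' gene is duplicated by RNA-mediated transposition into a new genomic
#' context, and the transposed copy evolves at twice the synonymous
#' rate.  The expected outcome mirrors a conserved syntelog group
#' spanning all species (outgroup included) and a faster-evolving,
#' intronless, ingroup-restricted group in a different context.
#'
#' @param seed Integer seed.
#' @return A [SimConfig-class].
#' @export
mammalScenario <- function(seed = 42L) {
  simConfig(
    tree = "((A:1,B:1,C:1,D:1,E:1,F:1)ingroup:1,OUT:2)root;",
    n_chromosomes = 2L, genes_per_chromosome = 40L,
    loss_rate = 0.02, tandem_rate = 0.01,
    transposition_rate = 0.005, inversion_rate = 0.01,
    rna_fraction = 0.5,
    forced_events = list(list(branch = "ingroup",
                              type = "rna_transposition",
                              family = "fam20")),
    family_of_interest = "fam20",
    ks_rate = 0.25, relaxed_multiplier = 2,
    seed = seed)
}

#' Plant-style scenario: whole-genome triplication plus one transposition
#'
#' Eight species sharing an ancestral whole-genome triplication with
#' fractionation (retention probability 0.6); on the stem of a
#' four-species clade one focal copy transposes (DNA-mediated) into a
#' new context.  The expected outcome is one syntenic supercluster
#' spanning all species plus one lineage-restricted community.
#'
#' @param seed Integer seed.
#' @return A [SimConfig-class].
#' @export
plantScenario <- function(seed = 42L) {
  simConfig(
    tree = paste0("((P1:1,P2:1,P3:1,P4:1)cladeA:1,",
                  "(P5:1,P6:1,P7:1,P8:1)cladeB:1)root;"),
    n_chromosomes = 2L, genes_per_chromosome = 40L,
    loss_rate = 0.02, tandem_rate = 0.01,
    transposition_rate = 0.005, inversion_rate = 0.005,
    rna_fraction = 0.2,
    wgd_events = list(list(branch = "root", multiplicity = 3,
                           retention_prob = 0.6)),
    forced_events = list(list(branch = "cladeB",
                              type = "dna_transposition",
                              family = "fam20")),
    family_of_interest = "fam20",
    ks_rate = 0.1, relaxed_multiplier = 1.5,
    seed = seed)
}
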