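#' @include AllClasses.R
NULL

#' Group homology hits into anchor sets by chromosome pair
#'
#' An anchor places a homologous gene pair at `(i, j)` = (rank on
#' chromosome A, rank on chromosome B).  Anchors are grouped by
#' unordered chromosome pair; intra-species and same-chromosome
#' comparisons are included, each unordered pair listed once (for
#' same-chromosome anchors `i < j`).
#'
#' @param genes A [GeneTable-class] covering every hit endpoint.
#' @param hits Filtered homology table (see [filterHomology()]).
#' @return Named list of anchor data.frames (`gene_a`, `gene_b`, `i`,
#'   `j`, `weight`), keyed `"speciesA.chrA|speciesB.chrB"` with the two
#'   sides in canonical order.
#' @export
buildAnchorSets <- function(genes, hits) {
  g <- geneRecords(genes)
  if (nrow(hits) == 0) return(list())
  idx <- match(hits$query_id, g$gene_id)
  jdx <- match(hits$subject_id, g$gene_id)
  if (anyNA(idx) || anyNA(jdx))
    stop("hit endpoint(s) missing from gene table: ",
         paste(head(c(hits$query_id[is.na(idx)],
                      hits$subject_id[is.na(jdx)]), 5), collapse = ", "))
  ca <- paste0(g$species[idx], ".", g$chrom[idx])
  cb <- paste0(g$species[jdx], ".", g$chrom[jdx])
  ra <- g$rank[idx]; rb <- g$rank[jdx]
  qa <- hits$query_id; qb <- hits$subject_id
  # orient each anchor so side a is the canonical-first chromosome;
  # on the same chromosome, i <= j
  swap <- ca > cb | (ca == cb & ra > rb)
  anc <- data.frame(
    key = paste(ifelse(swap, cb, ca), ifelse(swap, ca, cb), sep = "|"),
    gene_a = ifelse(swap, qb, qa), gene_b = ifelse(swap, qa, qb),
    i = ifelse(swap, rb, ra), j = ifelse(swap, ra, rb),
    weight = hits$bitscore, stringsAsFactors = FALSE)
  split(anc[, -1L], anc$key)
}

# Best monotone chain by dynamic programming over anchors sorted by
# (i, j).  orientation: +1 forward (j increasing), -1 inverted.
# Ties broken by longer chain, then smaller start i, then smaller start j.
.bestChain <- function(i, j, orientation, params) {
  m <- length(i)
  ms <- params@match_score; gp <- params@gap_penalty; mg <- params@max_gaps
  ord <- order(i, orientation * j)
  io <- i[ord]; jo <- j[ord]
  score <- rep(ms, m); len <- rep(1L, m); prev <- rep(0L, m)
  starti <- io; startj <- jo
  for (t in seq_len(m)) {
    if (t == 1L) next
    s <- seq_len(t - 1L)
    di <- io[t] - io[s] - 1L
    dj <- orientation * (jo[t] - jo[s]) - 1L
    ok <- di >= 0L & dj >= 0L & di <= mg & dj <= mg
    if (!any(ok)) next
    s <- s[ok]
    cand <- score[s] + ms + gp * (di[ok] + dj[ok])
    best <- order(-cand, -len[s], starti[s], startj[s])[1L]
    if (cand[best] > score[t] ||
        (cand[best] == score[t] && len[s[best]] + 1L > len[t])) {
      score[t] <- cand[best]
      len[t] <- len[s[best]] + 1L
      prev[t] <- s[best]
      starti[t] <- starti[s[best]]
      startj[t] <- startj[s[best]]
    }
  }
  end <- order(-score, -len, starti, startj)[1L]
  chain <- integer(0)
  t <- end
  while (t != 0L) {
    chain <- c(t, chain)
    t <- prev[t]
  }
  list(score = score[end], length = len[end], idx = ord[chain],
       start_i = starti[end], start_j = startj[end])
}

#' Chain anchors of one chromosome pair into collinear blocks
#'
#' Greedy best-chain extraction: the maximum-score monotone chain (chain
#' score = m * match_score + gap_penalty * sum of rank gaps, extensions
#' allowed only within `max_gaps` in both genomes) is found by dynamic
#' programming over both orientations; if it contains at least
#' `match_size` anchors it is emitted as a block and its anchors removed,
#' and the search repeats.  DP ties are broken by longer chain, then
#' smaller start `i`, then smaller start `j`; a forward chain is
#' preferred over an inverted chain of equal score and length.
#'
#' @param anchors Anchor data.frame for one chromosome pair (`gene_a`,
#'   `gene_b`, `i`, `j`), e.g. one element of [buildAnchorSets()].
#' @param params A [ChainParams-class].
#' @param chrom_pair Optional `"speciesA.chrA|speciesB.chrB"` key used
#'   to label blocks.
#' @return A [CollinearBlockSet-class] (empty input yields no blocks).
#' @examples
#' anc <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
#'                   i = 0:4, j = 0:4)
#' blocks(chainAnchors(anc, chainParams()))
#' @export
chainAnchors <- function(anchors, params = chainParams(),
                         chrom_pair = "A.chr|B.chr") {
  empty <- function() new(
    "CollinearBlockSet",
    blocks = data.frame(block_id = character(0), species_a = character(0),
                        chrom_a = character(0), species_b = character(0),
                        chrom_b = character(0), orientation = character(0),
                        score = numeric(0), n_anchors = integer(0)),
    anchors = data.frame(block_id = character(0), gene_a = character(0),
                         gene_b = character(0), i = integer(0),
                         j = integer(0)),
    params = params)
  out <- empty()
  if (is.null(anchors) || nrow(anchors) == 0) return(out)
  side <- strsplit(chrom_pair, "|", fixed = TRUE)[[1]]
  sp <- function(x) sub("\\.[^.]*$", "", x)
  ch <- function(x) sub("^.*\\.", "", x)
  anc <- anchors
  k <- 0L
  blocks <- list(); banchors <- list()
  while (nrow(anc) >= params@match_size) {
    fwd <- .bestChain(anc$i, anc$j, +1L, params)
    inv <- .bestChain(anc$i, anc$j, -1L, params)
    pickFwd <- fwd$score > inv$score ||
      (fwd$score == inv$score && fwd$length >= inv$length)
    best <- if (pickFwd) fwd else inv
    if (best$length < params@match_size) break
    k <- k + 1L
    bid <- sprintf("%s-%s#%d", side[1], side[2], k)
    rows <- anc[best$idx, , drop = FALSE]
    blocks[[k]] <- data.frame(
      block_id = bid, species_a = sp(side[1]), chrom_a = ch(side[1]),
      species_b = sp(side[2]), chrom_b = ch(side[2]),
      orientation = if (pickFwd) "forward" else "inverted",
      score = best$score, n_anchors = best$length,
      stringsAsFactors = FALSE)
    banchors[[k]] <- data.frame(block_id = bid, gene_a = rows$gene_a,
                                gene_b = rows$gene_b, i = rows$i,
                                j = rows$j, stringsAsFactors = FALSE)
    anc <- anc[-best$idx, , drop = FALSE]
  }
  if (k == 0L) return(out)
  new("CollinearBlockSet", blocks = do.call(rbind, blocks),
      anchors = do.call(rbind, banchors), params = params)
}

#' Detect tandem duplicate pairs and arrays
#'
#' A tandem pair is a homologous gene pair on the same chromosome of the
#' same species within `window` gene ranks; arrays are connected chains
#' of such pairs.
#'
#' @param genes A [GeneTable-class].
#' @param hits Filtered homology table.
#' @param window Maximum rank separation (default 1: adjacent genes).
#' @return A list with `pairs` (data.frame `gene_a`, `gene_b`) and
#'   `arrays` (list of member vectors, each a maximal connected chain).
#' @export
detectTandems <- function(genes, hits, window = 1L) {
  g <- geneRecords(genes)
  empty <- list(pairs = data.frame(gene_a = character(0),
                                   gene_b = character(0)),
                arrays = list())
  if (nrow(hits) == 0) return(empty)
  ia <- match(hits$query_id, g$gene_id)
  ib <- match(hits$subject_id, g$gene_id)
  same <- !is.na(ia) & !is.na(ib) &
    g$species[ia] == g$species[ib] & g$chrom[ia] == g$chrom[ib] &
    abs(g$rank[ia] - g$rank[ib]) <= window
  if (!any(same)) return(empty)
  cp <- .canonPair(hits$query_id[same], hits$subject_id[same])
  pairs <- unique(data.frame(gene_a = cp$a, gene_b = cp$b,
                             stringsAsFactors = FALSE))
  gph <- igraph::graph_from_data_frame(pairs, directed = FALSE)
  comp <- igraph::components(gph)
  arrays <- split(names(comp$membership), comp$membership)
  arrays <- unname(lapply(arrays, function(x) sort(x)))
  arrays <- arrays[order(-lengths(arrays),
                         vapply(arrays, `[[`, "", 1L))]
  list(pairs = pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE],
       arrays = arrays)
}

#' Detect collinear blocks for every genome pair
#'
#' Runs anchor chaining for every unordered species pair including
#' self-comparisons — exactly n(n+1)/2 comparisons for n genomes — and
#' returns all blocks together with a comparison manifest.
#'
#' @param genes A [GeneTable-class] covering all genomes, or a list of
#'   per-species tables (duplicate species identifiers are an error).
#' @param hits Filtered homology table.
#' @param params A [ChainParams-class].
#' @return List with `blocks` (a [CollinearBlockSet-class]) and
#'   `manifest` (data.frame `species_a`, `species_b`, `n_blocks`,
#'   `n_anchors`, one row per comparison).
#' @export
runAllPairs <- function(genes, hits, params = chainParams()) {
  if (is.list(genes) && !is(genes, "GeneTable"))
    genes <- combineGeneTables(genes)
  sps <- sort(speciesNames(genes))
  if (length(sps) < 1L) stop("no genomes in gene table")
  groups <- buildAnchorSets(genes, hits)
  sets <- lapply(names(groups), function(key)
    chainAnchors(groups[[key]], params, chrom_pair = key))
  blk <- do.call(rbind, c(list(chainAnchors(NULL, params)@blocks),
                          lapply(sets, blocks)))
  anc <- do.call(rbind, c(list(chainAnchors(NULL, params)@anchors),
                          lapply(sets, blockAnchors)))
  # disambiguate block ids across chromosome pairs is unnecessary: the
  # key is embedded in each id.  Build the species-level manifest.
  comb <- expand.grid(ai = seq_along(sps), bi = seq_along(sps))
  comb <- comb[comb$ai <= comb$bi, , drop = FALSE]
  manifest <- data.frame(species_a = sps[comb$ai], species_b = sps[comb$bi],
                         stringsAsFactors = FALSE)
  pk <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  bk <- pk(blk$species_a, blk$species_b)
  mk <- pk(manifest$species_a, manifest$species_b)
  manifest$n_blocks <- as.integer(table(factor(bk, levels = mk)))
  ak <- bk[match(anc$block_id, blk$block_id)]
  manifest$n_anchors <- as.integer(table(factor(ak, levels = mk)))
  list(blocks = new("CollinearBlockSet", blocks = blk, anchors = anc,
                    params = params),
       manifest = manifest)
}

#' Validate block invariants
#'
#' Checks, for every block: strictly increasing `i`; strictly monotone
#' `j` in the block's orientation; rank gaps within `max_gaps`; at least
#' `match_size` anchors; and that no anchor is claimed by two blocks of
#' the same chromosome pair.  Used by tests and callers as a guard.
#'
#' @param x A [CollinearBlockSet-class].
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validateBlocks <- function(x) {
  b <- blocks(x); a <- blockAnchors(x); p <- x@params
  for (r in seq_len(nrow(b))) {
    rows <- a[a$block_id == b$block_id[r], , drop = FALSE]
    if (nrow(rows) < p@match_size)
      stop("block ", b$block_id[r], " below match_size")
    if (any(diff(rows$i) <= 0))
      stop("block ", b$block_id[r], ": i not strictly increasing")
    dj <- diff(rows$j) * if (b$orientation[r] == "forward") 1L else -1L
    if (any(dj <= 0))
      stop("block ", b$block_id[r], ": j not strictly monotone")
    if (any(diff(rows$i) - 1L > p@max_gaps) || any(dj - 1L > p@max_gaps))
      stop("block ", b$block_id[r], ": gap exceeds max_gaps")
  }
  key <- paste(a$gene_a, a$gene_b, sep = "\r")
  pairkey <- paste(b$species_a, b$chrom_a, b$species_b,
                   b$chrom_b)[match(a$block_id, b$block_id)]
  if (anyDuplicated(paste(key, pairkey, sep = "\r")))
    stop("anchor assigned to two blocks of the same chromosome pair")
  invisible(TRUE)
}

#' Write blocks as a plain-text collinearity file
#'
#' One `## block` header (id, orientation, score) per block followed by
#' one tab-separated anchor pair per line.
#'
#' @param x A [CollinearBlockSet-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeCollinearity <- function(x, path) {
  b <- blocks(x); a <- blockAnchors(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in seq_len(nrow(b))) {
    writeLines(sprintf("## block %s orientation=%s score=%g",
                       b$block_id[r], b$orientation[r], b$score[r]), con)
    rows <- a[a$block_id == b$block_id[r], , drop = FALSE]
    writeLines(sprintf("%s\t%s\t%d\t%d", rows$gene_a, rows$gene_b,
                       rows$i, rows$j), con)
  }
  invisible(path)
}
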