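#' @include AllClasses.R
NULL

# Split GFF3 attribute strings into named character vectors.
.gffAttrs <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts)]
    kv <- strsplit(parts, "=", fixed = TRUE)
    setNames(vapply(kv, function(p) paste(p[-1], collapse = "="), ""),
             vapply(kv, `[[`, "", 1L))
  })
}

#' Read gene models from a GFF3 file
#'
#' Builds one record per gene.  Among a gene's isoforms the
#' representative is the transcript with the greatest summed CDS length
#' (falling back to summed exon length when a transcript carries no CDS
#' features), ties broken by the lexicographically smallest transcript
#' ID; `exon_count` is the number of exon features of that transcript
#' (CDS features are counted when it has no exon features).  GFF3
#' 1-based closed coordinates are converted to the internal 0-based
#' half-open convention at this boundary only.
#'
#' @param path GFF3 file.
#' @param species Species label; when `prefix = TRUE` gene identifiers
#'   become `"species|localId"` to guarantee cross-genome uniqueness.
#' @param prefix Prefix gene IDs with the species label (default TRUE).
#' @param feature_config Named list mapping the roles `gene`,
#'   `transcript`, `exon`, `cds` to GFF3 feature types.
#' @return A [GeneTable-class].  Genes without any transcript are
#'   excluded with a warning; an exon or CDS whose `Parent` cannot be
#'   resolved to a transcript is an error naming the offending line.
#' @export
readGff3 <- function(path, species,
                     prefix = TRUE,
                     feature_config = list(gene = "gene",
                                           transcript = c("mRNA",
                                                          "transcript"),
                                           exon = "exon", cds = "CDS")) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed GFF3 line ", lineno[bad[1]], " in ", path)
  f <- data.frame(
    seqid = vapply(fields, `[[`, "", 1L),
    type = vapply(fields, `[[`, "", 3L),
    start = as.integer(vapply(fields, `[[`, "", 4L)),
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    stringsAsFactors = FALSE)
  f$line <- lineno
  attrs <- .gffAttrs(vapply(fields, `[[`, "", 9L))
  f$id <- vapply(attrs, function(a) unname(a["ID"]), "")
  f$parent <- vapply(attrs, function(a) unname(a["Parent"]), "")

  is_gene <- f$type %in% feature_config$gene
  is_tx <- f$type %in% feature_config$transcript
  is_exon <- f$type %in% feature_config$exon
  is_cds <- f$type %in% feature_config$cds

  genes <- f[is_gene, , drop = FALSE]
  tx <- f[is_tx, , drop = FALSE]
  tx_of <- setNames(tx$parent, tx$id)

  resolveParent <- function(sub, what) {
    # Parent may list several transcripts; keep resolvable ones.
    plist <- strsplit(sub$parent, ",", fixed = TRUE)
    ok <- vapply(plist, function(p) any(p %in% tx$id), NA)
    ok[is.na(sub$parent)] <- FALSE
    if (any(!ok))
      stop(what, " without resolvable Parent at line ",
           sub$line[which(!ok)[1]], " in ", path)
    vapply(plist, function(p) p[p %in% tx$id][1], "")
  }
  exons <- f[is_exon, , drop = FALSE]
  cds <- f[is_cds, , drop = FALSE]
  exons$tx <- if (nrow(exons)) resolveParent(exons, "exon") else character(0)
  cds$tx <- if (nrow(cds)) resolveParent(cds, "CDS") else character(0)

  exon_len <- tapply(exons$end - exons$start + 1L, exons$tx, sum)
  cds_len <- tapply(cds$end - cds$start + 1L, cds$tx, sum)
  exon_n <- tapply(exons$tx, exons$tx, length)
  cds_n <- tapply(cds$tx, cds$tx, length)

  pick <- function(gene_id) {
    tids <- tx$id[tx$parent == gene_id]
    if (!length(tids)) return(NA_character_)
    len <- ifelse(!is.na(cds_len[tids]), cds_len[tids], exon_len[tids])
    len[is.na(len)] <- 0
    tids[order(-len, tids)][1]
  }
  chosen <- vapply(genes$id, pick, "")
  if (any(is.na(chosen))) {
    warning("excluding ", sum(is.na(chosen)),
            " gene(s) without any transcript: ",
            paste(head(genes$id[is.na(chosen)], 5), collapse = ", "))
    genes <- genes[!is.na(chosen), , drop = FALSE]
    chosen <- chosen[!is.na(chosen)]
  }
  n_exons <- ifelse(!is.na(exon_n[chosen]), exon_n[chosen], cds_n[chosen])
  local_id <- genes$id
  makeGeneTable(data.frame(
    gene_id = if (prefix) paste0(species, "|", local_id) else local_id,
    species = species,
    chrom = genes$seqid,
    start = genes$start - 1L,   # 1-based closed -> 0-based half-open
    end = genes$end,
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "+"),
    exon_count = as.integer(n_exons),
    stringsAsFactors = FALSE))
}

#' Write gene models as GFF3
#'
#' Inverse of [readGff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based closed at the file boundary, so a
#' round-trip restores the original intervals exactly.  When
#' `exon_count` and CDS lengths are available, gene/mRNA/exon/CDS
#' features are emitted (exons tile the coding sequence, separated by
#' fixed 100-bp introns); otherwise a minimal gene model with a single
#' spanning exon is written.
#'
#' @param genes A [GeneTable-class].
#' @param path Output file.
#' @param cds Optional named character vector of coding sequences (names
#'   are gene ids) used to lay out exon/CDS features.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(genes, path, cds = NULL) {
  g <- geneRecords(genes)
  local <- sub("^[^|]*\\|", "", g$gene_id)
  out <- c("##gff-version 3")
  for (r in seq_len(nrow(g))) {
    id <- local[r]
    gl <- sprintf("%s\tmsynnet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  g$chrom[r], g$start[r] + 1L, g$end[r], g$strand[r], id)
    out <- c(out, gl)
    nex <- g$exon_count[r]
    seqr <- if (!is.null(cds)) cds[[g$gene_id[r]]] else NULL
    if (is.na(nex) || is.null(seqr)) {
      # no exon layout known: minimal gene model (mRNA + spanning exon)
      tid <- paste0(id, ".t1")
      out <- c(out, sprintf(
        "%s\tmsynnet\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom[r], g$start[r] + 1L, g$end[r], g$strand[r], tid, id), sprintf(
        "%s\tmsynnet\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        g$chrom[r], g$start[r] + 1L, g$end[r], g$strand[r], tid))
    } else if (!is.na(nex) && !is.null(seqr)) {
      tid <- paste0(id, ".t1")
      out <- c(out, sprintf(
        "%s\tmsynnet\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom[r], g$start[r] + 1L, g$end[r], g$strand[r], tid, id))
      len <- nchar(seqr)
      sizes <- rep(len %/% nex, nex)
      if (len %% nex > 0) sizes[seq_len(len %% nex)] <- sizes[seq_len(len %% nex)] + 1L
      s <- g$start[r] + 1L
      for (e in seq_len(nex)) {
        out <- c(out, sprintf(
          "%s\tmsynnet\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          g$chrom[r], s, s + sizes[e] - 1L, g$strand[r], tid), sprintf(
          "%s\tmsynnet\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
          g$chrom[r], s, s + sizes[e] - 1L, g$strand[r], tid))
        s <- s + sizes[e] + 100L
      }
    }
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Read gene positions from a BED file
#'
#' BED is already 0-based half-open, so coordinates are taken as-is;
#' column 4 is the gene id and `exon_count` is absent.
#'
#' @param path BED4 or BED6 file.
#' @param species Species label (prefixes gene ids when `prefix = TRUE`).
#' @param prefix Prefix gene ids with the species label.
#' @return A [GeneTable-class]; an empty file yields an empty table with
#'   a warning.  A record with `start >= end` is an error naming the
#'   line.
#' @export
readBed <- function(path, species, prefix = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    warning("empty BED file: ", path)
    return(makeGeneTable(data.frame(
      gene_id = character(0), species = character(0), chrom = character(0),
      start = integer(0), end = integer(0), strand = character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("BED line ", which(lengths(fields) < 4L)[1], " has fewer than 4 columns")
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  if (any(start >= end))
    stop("start >= end at BED line ", which(start >= end)[1], " in ", path)
  strand <- vapply(fields, function(x) if (length(x) >= 6) x[[6]] else "+", "")
  strand[!strand %in% c("+", "-")] <- "+"
  ids <- vapply(fields, `[[`, "", 4L)
  makeGeneTable(data.frame(
    gene_id = if (prefix) paste0(species, "|", ids) else ids,
    species = species,
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end, strand = strand,
    stringsAsFactors = FALSE))
}

#' Write gene positions as BED6
#'
#' @param genes A [GeneTable-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(genes, path) {
  g <- geneRecords(genes)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, g$start, g$end,
                     sub("^[^|]*\\|", "", g$gene_id), g$strand), path)
  invisible(path)
}

#' Filter a homology hit table
#'
#' Applies the protocol filters in order: self hits are removed, hits
#' above the e-value ceiling are removed, and each gene retains its top
#' `maxHits` partners by bitscore (ties by partner id); a pair survives
#' when both endpoints retain it (the reciprocal reading of an
#' all-against-all search with a capped hit list), making the edge set
#' order independent.  The result lists each unordered pair once,
#' canonically ordered, with the best bitscore / smallest e-value across
#' directions.  The filter is idempotent: removing a pair can only move
#' the survivors up each gene's ranking.
#'
#' @param hits data.frame with `query_id`, `subject_id`, `bitscore`,
#'   `evalue`.
#' @param evalueMax E-value ceiling (default `1e-10`).
#' @param maxHits Retained partners per gene (default 20, the hit-list
#'   cap of the all-vs-all search protocol).
#' @param genes Optional [GeneTable-class] used to check hit endpoints.
#' @param unknown What to do with hits whose genes are absent from
#'   `genes`: `"error"` or `"skip"` (with a warning).
#' @return Filtered, symmetrized data.frame.
#' @export
filterHomology <- function(hits, evalueMax = 1e-10, maxHits = 20L,
                           genes = NULL, unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  if (!is.null(genes)) {
    known <- geneIds(genes)
    bad <- !(hits$query_id %in% known & hits$subject_id %in% known)
    if (any(bad)) {
      offenders <- unique(c(hits$query_id[bad], hits$subject_id[bad]))
      offenders <- setdiff(offenders, known)
      if (unknown == "error")
        stop("unknown gene id(s) in homology table: ",
             paste(head(offenders, 5), collapse = ", "))
      warning("skipping ", sum(bad), " hit(s) with unknown gene id(s): ",
              paste(head(offenders, 5), collapse = ", "))
      hits <- hits[!bad, , drop = FALSE]
    }
  }
  if (nrow(hits) == 0)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      bitscore = numeric(0), evalue = numeric(0)))
  # collapse to canonical unordered pairs, best score per pair
  cp <- .canonPair(hits$query_id, hits$subject_id)
  key <- paste(cp$a, cp$b, sep = "\r")
  ord <- order(key, -hits$bitscore, hits$evalue)
  hits <- data.frame(query_id = cp$a[ord], subject_id = cp$b[ord],
                     bitscore = hits$bitscore[ord], evalue = hits$evalue[ord],
                     stringsAsFactors = FALSE)
  hits <- hits[!duplicated(paste(hits$query_id, hits$subject_id, sep = "\r")),
               , drop = FALSE]
  # reciprocal per-gene top-maxHits: both endpoints must rank the pair
  long <- rbind(
    data.frame(gene = hits$query_id, partner = hits$subject_id,
               bitscore = hits$bitscore, pair = seq_len(nrow(hits))),
    data.frame(gene = hits$subject_id, partner = hits$query_id,
               bitscore = hits$bitscore, pair = seq_len(nrow(hits))))
  long <- long[order(long$gene, -long$bitscore, long$partner), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(long)), long$gene, FUN = seq_along)
  ok <- tapply(idx <= maxHits, long$pair, all)
  keep_pairs <- as.integer(names(ok))[ok]
  out <- hits[sort(keep_pairs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a 12-column tabular homology table
#'
#' Columns 1, 2, 11, 12 are query, subject, e-value, bitscore (the
#' blast `outfmt 6` dialect).  The table is filtered and symmetrized by
#' [filterHomology()].
#'
#' @inheritParams filterHomology
#' @param path Tabular hits file.
#' @return Filtered data.frame of unordered pairs.
#' @export
readHomologyTable <- function(path, evalueMax = 1e-10, maxHits = 20L,
                              genes = NULL, unknown = c("error", "skip")) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 12)
    stop("expected 12 tab-separated columns in ", path)
  hits <- data.frame(query_id = as.character(raw[[1]]),
                     subject_id = as.character(raw[[2]]),
                     bitscore = as.numeric(raw[[12]]),
                     evalue = as.numeric(raw[[11]]),
                     stringsAsFactors = FALSE)
  filterHomology(hits, evalueMax = evalueMax, maxHits = maxHits,
                 genes = genes, unknown = unknown)
}

#' Write homology hits in the 12-column tabular dialect
#'
#' Placeholder alignment statistics are emitted for the columns the
#' pipeline does not use (percent identity, alignment length, mismatch,
#' gap and coordinate columns).
#'
#' @param hits data.frame with `query_id`, `subject_id`, `bitscore`,
#'   `evalue`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeHomologyTable <- function(hits, path) {
  writeLines(sprintf("%s\t%s\t%.1f\t%d\t0\t0\t1\t%d\t1\t%d\t%.3g\t%.1f",
                     hits$query_id, hits$subject_id, 100.0, 300L, 300L,
                     300L, hits$evalue, hits$bitscore), path)
  invisible(path)
}

#' Read/write FASTA sequences as a named character vector
#'
#' Sequence ids are the token before the first whitespace; duplicate ids
#' are an error.
#'
#' @param path FASTA file.
#' @return `readFasta()`: named character vector.
#' @export
readFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(as.character(set), ids)
}

#' @param seqs Named character vector of sequences.
#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
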