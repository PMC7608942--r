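#' @include AllClasses.R
NULL

# --- genetic-code machinery (standard code only) ---------------------------

.NT <- c("A", "C", "G", "T")

.codonTable <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- as.character(gc)
  names(aa) <- codons
  aa
})

.SENSE <- names(.codonTable)[.codonTable != "*"]

# For each sense codon: matrix of synonymous single-nucleotide options
# (rows: position 1..3, alternative nucleotide), and the NG86 synonymous
# site count (#synonymous one-step changes / 3; changes to stop codons
# count as nonsynonymous).
.synOptions <- local({
  out <- list()
  for (cod in .SENSE) {
    nts <- strsplit(cod, "")[[1]]
    opts <- NULL
    for (pos in 1:3) {
      for (alt in setdiff(.NT, nts[pos])) {
        mut <- nts
        mut[pos] <- alt
        mcod <- paste(mut, collapse = "")
        if (.codonTable[[mcod]] == .codonTable[[cod]])
          opts <- rbind(opts, c(pos, alt))
      }
    }
    out[[cod]] <- opts
  }
  out
})

.synSites <- vapply(.SENSE, function(cod) {
  n <- if (is.null(.synOptions[[cod]])) 0L else nrow(.synOptions[[cod]])
  n / 3
}, 0)

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Amino-acid string (stop codons become `*`).
#' @export
translateCds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(unname(.codonTable[toupper(codons)]), collapse = "")
}

# --- NG86 difference counting ----------------------------------------------

.ng86_cache <- new.env(parent = emptyenv(), hash = TRUE)

# Average synonymous/nonsynonymous difference counts between two sense
# codons over all minimal substitution pathways, equal pathway weights;
# pathways passing through stop codons are excluded (if every pathway is
# blocked, all pathways are used and stop-crossing steps count as
# nonsynonymous).
.codonDiff <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  dpos <- which(n1 != n2)
  res <- if (length(dpos) == 0L) {
    c(sd = 0, nd = 0)
  } else {
    perms <- if (length(dpos) == 1L) list(dpos) else {
      p <- list()
      rec <- function(left, acc) {
        if (!length(left)) {
          p[[length(p) + 1L]] <<- acc
        } else for (x in left) rec(setdiff(left, x), c(acc, x))
      }
      rec(dpos, integer(0))
      p
    }
    walk <- function(path, allowStops) {
      cur <- n1
      sd <- 0; nd <- 0
      for (pos in path) {
        nxt <- cur
        nxt[pos] <- n2[pos]
        a1 <- .codonTable[[paste(cur, collapse = "")]]
        a2 <- .codonTable[[paste(nxt, collapse = "")]]
        if (!allowStops && (a1 == "*" || a2 == "*")) return(NULL)
        if (a1 == a2 && a1 != "*") sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    counts <- Filter(Negate(is.null), lapply(perms, walk, allowStops = FALSE))
    if (!length(counts))
      counts <- lapply(perms, walk, allowStops = TRUE)
    Reduce(`+`, counts) / length(counts)
  }
  .ng86_cache[[key]] <- res
  res
}

#' Nei-Gojobori (1986) Ka/Ks estimate from a codon alignment
#'
#' Site counting: each codon's synonymous site fraction is the number of
#' synonymous one-step changes divided by 3, summed over codons and
#' averaged between the two sequences (S), with N = 3n - S.
#' Differences are counted over all minimal substitution pathways with
#' equal weights, pathways through stop codons excluded.  The raw
#' proportions ps = Sd/S and pn = Nd/N are Jukes-Cantor corrected:
#' Ks = -(3/4) log(1 - (4/3) ps), likewise Ka.  When the logarithm's
#' argument is non-positive the synonymous distance is undefined and the
#' pair is flagged `saturated` (likewise Ka is set to `NA`).
#'
#' Codon columns containing gaps, ambiguity codes or stop codons are
#' excluded from all counts; the number excluded is reported.
#'
#' @param aln A codon alignment: list with elements `codon1`, `codon2`
#'   (equal-length strings over `ACGT-`, length divisible by 3), as
#'   returned by [backtranslate()]; or two raw CDS strings of equal
#'   length given as `aln` and `aln2`.
#' @param aln2 Optional second sequence (see above).
#' @return One-row data.frame: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `Ka`,
#'   `Ks`, `omega` (`NA` when Ks is 0 or undefined), `saturated`,
#'   `n_codons` (comparable codons), `n_excluded`.
#' @examples
#' ng86("GGGGGGGGG", "GGAGGGGGG")   # Sd = 1, Ks ~ 0.4408, Ka = 0
#' @export
ng86 <- function(aln, aln2 = NULL) {
  if (!is.null(aln2)) aln <- list(codon1 = aln, codon2 = aln2)
  s1 <- toupper(aln$codon1); s2 <- toupper(aln$codon2)
  if (nchar(s1) != nchar(s2)) stop("aligned sequences differ in length")
  if (nchar(s1) %% 3 != 0) stop("alignment length not divisible by 3")
  starts <- seq(1, nchar(s1), 3)
  cod1 <- substring(s1, starts, starts + 2)
  cod2 <- substring(s2, starts, starts + 2)
  ok <- cod1 %in% .SENSE & cod2 %in% .SENSE
  n_excl <- sum(!ok)
  if (n_excl > 0)
    message("ng86: excluding ", n_excl,
            " codon column(s) with gaps, ambiguity codes or stops")
  cod1 <- cod1[ok]; cod2 <- cod2[ok]
  n <- length(cod1)
  if (n == 0) stop("no comparable codons in alignment")
  S <- (sum(.synSites[cod1]) + sum(.synSites[cod2])) / 2
  N <- 3 * n - S
  diffs <- mapply(function(a, b) .codonDiff(a, b), cod1, cod2)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -0.75 * log(arg) + 0  # +0 drops signed zero
  }
  Ks <- jc(ps)
  Ka <- jc(pn)
  saturated <- is.na(Ks)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
             Ka = Ka, Ks = Ks, omega = omega, saturated = saturated,
             n_codons = n, n_excluded = n_excl)
}

# --- alignment and back-translation ----------------------------------------

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

#' Global protein alignment (Needleman-Wunsch, BLOSUM62, affine gaps)
#'
#' Gap open 10, gap extend 0.5; the traceback is deterministic.
#'
#' @param p1,p2 Non-empty amino-acid strings; a symbol outside the
#'   amino-acid alphabet is an error.
#' @return List with `a1`, `a2` (aligned strings with `-` gaps) and
#'   `score`.
#' @export
alignProteins <- function(p1, p2) {
  if (!nzchar(p1) || !nzchar(p2)) stop("empty protein sequence")
  alphabet <- setdiff(rownames(.blosum62), "*")
  for (p in c(p1, p2)) {
    bad <- setdiff(strsplit(toupper(p), "")[[1]], alphabet)
    if (length(bad))
      stop("non-amino-acid symbol(s) in protein sequence: ",
           paste(unique(bad), collapse = ", "))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(p1)), Biostrings::AAString(toupper(p2)),
    type = "global", substitutionMatrix = .blosum62,
    gapOpening = 10, gapExtension = 0.5)
  list(a1 = as.character(Biostrings::alignedPattern(pa)),
       a2 = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

.stripStop <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  last <- substring(cds, nchar(cds) - 2, nchar(cds))
  if (.codonTable[[last]] == "*") substring(cds, 1, nchar(cds) - 3) else cds
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue is replaced by its source codon and each gap by `---`.
#' One terminal stop codon is stripped from each CDS before checking;
#' the degapped protein must equal the CDS translation exactly, and an
#' internal stop codon is an error.
#'
#' @param alignment List with aligned strings `a1`, `a2` (from
#'   [alignProteins()]).
#' @param cds1,cds2 Coding sequences of the two proteins.
#' @param ids Optional character vector of length 2 naming the genes
#'   (used in error messages and carried along).
#' @return A codon alignment: list with `codon1`, `codon2`, `ids`.
#' @export
backtranslate <- function(alignment, cds1, cds2, ids = c("seq1", "seq2")) {
  one <- function(aa_aln, cds, id) {
    cds <- .stripStop(cds)
    aa <- gsub("-", "", aa_aln, fixed = TRUE)
    if (nchar(cds) != 3 * nchar(aa))
      stop("CDS length of ", id, " does not match its protein (",
           nchar(cds), " nt vs ", nchar(aa), " aa)")
    tr <- translateCds(cds)
    if (grepl("*", tr, fixed = TRUE))
      stop("internal stop codon in CDS of ", id)
    if (tr != toupper(aa))
      stop("translation of CDS does not match protein for ", id)
    starts <- seq(1, nchar(cds), 3)
    codons <- substring(cds, starts, starts + 2)
    out <- character(nchar(aa_aln))
    ci <- 0L
    chars <- strsplit(aa_aln, "")[[1]]
    for (p in seq_along(chars)) {
      if (chars[p] == "-") {
        out[p] <- "---"
      } else {
        ci <- ci + 1L
        out[p] <- codons[ci]
      }
    }
    paste(out, collapse = "")
  }
  list(codon1 = one(alignment$a1, cds1, ids[1]),
       codon2 = one(alignment$a2, cds2, ids[2]),
       ids = ids)
}

#' Number of unordered pairs among n items
#'
#' @param n Non-negative integer.
#' @return `n (n - 1) / 2`.
#' @examples
#' countPairs(60)  # 1770
#' countPairs(73)  # 2628
#' @export
countPairs <- function(n) {
  stopifnot(n >= 0)
  as.numeric(n) * (n - 1) / 2
}

#' Pairwise Ks estimation and summaries per syntelog group
#'
#' For every group, all C(n, 2) gene pairs are protein-aligned,
#' back-translated and NG86-estimated.  Saturated pairs are excluded
#' from the mean and quartiles but reported in `n_saturated` so the
#' exclusion is visible.  Quartiles use linear interpolation between
#' order statistics.
#'
#' @param groups Named list of gene-id vectors (e.g. community member
#'   lists).  Groups of fewer than 2 genes are skipped with a warning.
#' @param cds Named character vector of coding sequences.
#' @param proteins Optional named character vector of protein sequences;
#'   derived by translation (with terminal stop stripped) when missing.
#' @return List with `pairs` (per-pair table: `group`, `gene_a`,
#'   `gene_b`, and the [ng86()] fields) and `summary` (per group:
#'   `n_pairs`, `n_saturated`, `mean_ks`, `q1_ks`, `median_ks`,
#'   `q3_ks`).
#' @export
groupKs <- function(groups, cds, proteins = NULL) {
  if (is.null(proteins))
    proteins <- vapply(cds, function(x) translateCds(.stripStop(x)), "")
  pairRows <- list(); sumRows <- list()
  for (nm in names(groups)) {
    ids <- groups[[nm]]
    if (length(ids) < 2) {
      warning("group ", nm, " has fewer than 2 genes; skipped")
      next
    }
    missing <- setdiff(ids, names(cds))
    if (length(missing))
      stop("no CDS for gene(s): ", paste(head(missing, 5), collapse = ", "))
    pr <- combn(sort(ids), 2)
    est <- lapply(seq_len(ncol(pr)), function(c) {
      a <- pr[1, c]; b <- pr[2, c]
      aln <- alignProteins(proteins[[a]], proteins[[b]])
      cal <- backtranslate(aln, cds[[a]], cds[[b]], ids = c(a, b))
      cbind(data.frame(group = nm, gene_a = a, gene_b = b,
                       stringsAsFactors = FALSE),
            suppressMessages(ng86(cal)))
    })
    est <- do.call(rbind, est)
    pairRows[[nm]] <- est
    ks <- est$Ks[!est$saturated]
    q <- if (length(ks)) quantile(ks, c(0.25, 0.5, 0.75), type = 7)
         else rep(NA_real_, 3)
    sumRows[[nm]] <- data.frame(
      group = nm, n_pairs = ncol(pr), n_saturated = sum(est$saturated),
      mean_ks = if (length(ks)) mean(ks) else NA_real_,
      q1_ks = q[[1]], median_ks = q[[2]], q3_ks = q[[3]],
      stringsAsFactors = FALSE)
  }
  list(pairs = if (length(pairRows)) do.call(rbind, c(pairRows,
         list(make.row.names = FALSE))) else NULL,
       summary = if (length(sumRows)) do.call(rbind, c(sumRows,
         list(make.row.names = FALSE))) else NULL)
}
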