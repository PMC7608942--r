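# Internal helpers shared across modules.

# Deterministic 31-bit hash of a string, used to derive per-branch RNG
# substreams so that tree traversal order cannot change simulation output.
.hashString <- function(x) {
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

.deriveSeed <- function(seed, label) {
  as.integer((as.numeric(seed) * 7919 + .hashString(label)) %% 2147483647)
}

# Canonical (lexicographically ordered) representation of unordered pairs.
.canonPair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Write a table as tab-separated text with a commented header
#'
#' All table writers in the package emit UTF-8 tab-separated files whose
#' single header line is prefixed with `"# "`; [readTsv()] reverses this.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", paste(colnames(x), collapse = "\t")), con)
  if (nrow(x) > 0)
    write.table(x, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [writeTsv()]
#'
#' @param path File path.
#' @return A data frame; zero rows if the file holds only the header.
#' @export
readTsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  cols <- strsplit(sub("^#\\s*", "", lines[1L]), "\t", fixed = TRUE)[[1]]
  if (length(lines) < 2L)
    return(as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE))
  read.delim(text = lines[-1L], header = FALSE, sep = "\t",
             col.names = cols, stringsAsFactors = FALSE, comment.char = "")
}
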