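# Tiny in-code fixtures for the IO tests.

writeGffFixture <- function(path) {
  writeLines(c(
    "##gff-version 3",
    # gene g1: two isoforms, CDS lengths 300 (t1, 2 exons) and 450 (t2, 3 exons)
    "chr1\tsrc\tgene\t101\t1100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t700\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t101\t250\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\texon\t551\t700\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t101\t250\t.\t+\t0\tParent=g1.t1",
    "chr1\tsrc\tCDS\t551\t700\t.\t+\t0\tParent=g1.t1",
    "chr1\tsrc\tmRNA\t101\t1100\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tsrc\texon\t101\t250\t.\t+\t.\tParent=g1.t2",
    "chr1\tsrc\texon\t551\t700\t.\t+\t.\tParent=g1.t2",
    "chr1\tsrc\texon\t951\t1100\t.\t+\t.\tParent=g1.t2",
    "chr1\tsrc\tCDS\t101\t250\t.\t+\t0\tParent=g1.t2",
    "chr1\tsrc\tCDS\t551\t700\t.\t+\t0\tParent=g1.t2",
    "chr1\tsrc\tCDS\t951\t1100\t.\t+\t0\tParent=g1.t2",
    # gene g2: one isoform, 9 exons (no CDS -> exon fallback)
    "chr1\tsrc\tgene\t2001\t2900\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t2001\t2900\t.\t-\t.\tID=g2.t1;Parent=g2",
    vapply(0:8, function(k) sprintf(
      "chr1\tsrc\texon\t%d\t%d\t.\t-\t.\tParent=g2.t1",
      2001 + k * 100, 2050 + k * 100), "")
  ), path)
  path
}

# minimal 12-column homology line
hitLine <- function(q, s, evalue, bits)
  sprintf("%s\t%s\t95.0\t200\t5\t0\t1\t200\t1\t200\t%g\t%g", q, s, evalue, bits)

# small two-species gene table on one chromosome each, same gene order
twoSpeciesGenes <- function(n = 8) {
  rows <- do.call(rbind, lapply(c("A", "B"), function(sp)
    data.frame(gene_id = paste0(sp, "|g", seq_len(n)), species = sp,
               chrom = "chr1", start = (seq_len(n) - 1L) * 100L,
               end = (seq_len(n) - 1L) * 100L + 50L, strand = "+",
               stringsAsFactors = FALSE)))
  makeGeneTable(rows)
}

orthoHits <- function(n = 8, bits = 400) {
  data.frame(query_id = paste0("A|g", seq_len(n)),
             subject_id = paste0("B|g", seq_len(n)),
             bitscore = bits, evalue = 1e-50, stringsAsFactors = FALSE)
}
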