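# Independent oracles used across the suite. All work from first principles
# (binomial coefficients, exhaustive enumeration) and never call the package
# functions they check.

# hypergeometric pmf over the support of a 2x2 table with fixed margins,
# computed from binomial coefficients
table_pmf <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  N <- a + b + c + d
  supp <- max(0, r1 - c2):min(r1, c1)
  pr <- choose(c1, supp) * choose(c2, r1 - supp) / choose(N, r1)
  list(support = supp, prob = pr)
}

# two-sided mid-p by direct pmf enumeration
midp_oracle <- function(a, b, c, d) {
  pm <- table_pmf(a, b, c, d)
  peq <- pm$prob[pm$support == a]
  up <- sum(pm$prob[pm$support > a]) + 0.5 * peq
  lo <- sum(pm$prob[pm$support < a]) + 0.5 * peq
  min(1, 2 * min(up, lo))
}

# two-sided Fisher exact p (minimal-likelihood definition) by enumeration
fisher_oracle <- function(a, b, c, d) {
  pm <- table_pmf(a, b, c, d)
  peq <- pm$prob[pm$support == a]
  sum(pm$prob[pm$prob <= peq * (1 + 1e-7)])
}

# upper-tail overlap probability by exhaustive enumeration of all size-n
# subsets of 1..N against the fixed set 1..K
overlap_enum_oracle <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  ov <- colSums(sets <= K)
  mean(ov >= k)
}

# random 2x2 tables with margins bounded by `max_margin`
random_tables <- function(n, max_margin, seed) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    r1 <- sample.int(max_margin, 1)
    r2 <- sample.int(max_margin, 1)
    a <- sample.int(r1 + 1L, 1) - 1L
    c_ <- sample.int(r2 + 1L, 1) - 1L
    c(a, r1 - a, c_, r2 - c_)
  }, integer(4)))
}

# tiny in-memory sync builder: one scaffold, counts given as a list of
# two-pool sextet pairs
make_sync <- function(pos, pool1, pool2, scaffold = "scf1", ref = "A") {
  stopifnot(length(pos) == nrow(pool1), nrow(pool1) == nrow(pool2))
  colnames(pool1) <- colnames(pool2) <- c("A", "T", "C", "G", "N", "del")
  paradapt:::new_sync(
    data.frame(scaffold = scaffold, pos = as.integer(pos),
               ref = rep_len(ref, length(pos)), stringsAsFactors = FALSE),
    list(pool1, pool2))
}

# sextet row helper
sx <- function(A = 0, T = 0, C = 0, G = 0, N = 0, del = 0)
  c(A, T, C, G, N, del)

# write a minimal single-gene GFF3 + FASTA pair for annotation tests
write_test_gene <- function(dir, scaffold_seq, gene_id, strand, segs,
                            scaffold = "chr1") {
  fa <- file.path(dir, "g.fasta")
  writeLines(c(paste0(">", scaffold), scaffold_seq), fa)
  mrna <- paste0(gene_id, ".t1")
  tx_start <- min(segs$start); tx_end <- max(segs$end)
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     scaffold, tx_start, tx_end, strand, gene_id),
             sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     scaffold, tx_start, tx_end, strand, mrna, gene_id))
  for (i in seq_len(nrow(segs))) {
    ph <- if (!is.null(segs$phase)) segs$phase[i] else 0L
    phs <- if (segs$type[i] == "CDS") as.character(ph) else "."
    lines <- c(lines,
               sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
                       scaffold, segs$type[i], segs$start[i], segs$end[i],
                       strand, phs, mrna))
  }
  gff <- file.path(dir, "g.gff3")
  writeLines(lines, gff)
  list(fasta = fa, gff = gff)
}
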