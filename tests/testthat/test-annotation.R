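make_fwd_gene <- function(dir) {
  # scaffold 400 bp; gene: 5'UTR 61-100, CDS 101-160, intron 161-200,
  # CDS 201-230, 3'UTR 231-270
  set.seed(77)
  seqc <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  segs <- data.frame(type = c("five_prime_UTR", "CDS", "CDS",
                              "three_prime_UTR"),
                     start = c(61, 101, 201, 231),
                     end = c(100, 160, 230, 270))
  p <- write_test_gene(dir, seqc, "gf", "+", segs)
  list(seq = seqc, paths = p)
}

test_that("coding SNPs are classified through the genetic code, both strands", {
  d <- withr::local_tempdir()
  # plus strand: plant ATG at CDS start, mutate third position
  seqc <- paste0(strrep("A", 100), "ATG", strrep("C", 57),
                 strrep("G", 40), strrep("T", 100))
  segs <- data.frame(type = "CDS", start = 101, end = 160)
  p <- write_test_gene(d, seqc, "g1", "+", segs)
  genome <- read_genome_fasta(p$fasta)
  gm <- read_gff3(p$gff, genome)
  # ATG -> ATA: Met -> Ile, nonsynonymous
  expect_equal(classify_effect("chr1", 103, "G", "A", "g1", gm, genome),
               "nonsynonymous")
  # CTG -> CTA: Leu -> Leu, synonymous (plant CTG by mutating ref? use codon 2:
  # codon 2 is CCC -> CCA synonymous Pro)
  expect_equal(classify_effect("chr1", 106, "C", "A", "g1", gm, genome),
               "synonymous")
  # reference mismatch is an error
  expect_error(classify_effect("chr1", 103, "T", "A", "g1", gm, genome),
               "mismatch")

  # minus strand: genomic C->T at a site whose transcript codon is GAG->GAA
  # (Glu -> Glu, synonymous). Transcript CTC at genomic 101-103 (minus) reads
  # GAG; genomic 101 C is the codon's third position.
  seqc2 <- paste0(strrep("A", 100), "CTC", strrep("CTC", 19), strrep("T", 100))
  segs2 <- data.frame(type = "CDS", start = 101, end = 160)
  p2 <- write_test_gene(d, seqc2, "g2", "-", segs2)
  genome2 <- read_genome_fasta(p2$fasta)
  gm2 <- read_gff3(p2$gff, genome2)
  expect_equal(classify_effect("chr1", 101, "C", "T", "g2", gm2, genome2),
               "synonymous")
  # and the codon's middle position: GAG -> GTG? genomic 102 T->A gives
  # transcript A at middle: GAG -> GUG? complement of A is T... genomic T->G
  # makes transcript middle C: GCG Ala, nonsynonymous
  expect_equal(classify_effect("chr1", 102, "T", "G", "g2", gm2, genome2),
               "nonsynonymous")
})

test_that("non-coding classes follow containment with the priority rule", {
  d <- withr::local_tempdir()
  g <- make_fwd_gene(d)
  genome <- read_genome_fasta(g$paths$fasta)
  gm <- read_gff3(g$paths$gff, genome)
  base_at <- function(i) substr(g$seq, i, i)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  cls <- function(pos) classify_effect("chr1", pos, base_at(pos),
                                       other(base_at(pos)), "gf", gm, genome)
  expect_equal(cls(80), "UTR5")
  expect_equal(cls(250), "UTR3")
  expect_equal(cls(180), "intronic")
  expect_equal(cls(30), "flanking")   # upstream of tx but within 1 kb
  expect_true(cls(120) %in% c("synonymous", "nonsynonymous"))
})

test_that("gene assignment spans the transcript plus a 1-kb inclusive flank", {
  d <- withr::local_tempdir()
  set.seed(5)
  seqc <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                collapse = "")
  segs <- data.frame(type = "CDS", start = 2001, end = 2600)
  p <- write_test_gene(d, seqc, "g1", "+", segs)
  genome <- read_genome_fasta(p$fasta)
  gm <- read_gff3(p$gff, genome)
  snps <- data.frame(scaffold = "chr1",
                     pos = c(1500, 1001, 1000, 3600, 3601, 2100))
  asg <- assign_snp_to_genes(snps, gm)
  expect_setequal(asg$snp_idx, c(1, 2, 4, 6))  # 1000 and 3601 are > 1 kb away
  # a SNP 500 bp upstream is flanking
  expect_equal(classify_effect("chr1", 1500, substr(seqc, 1500, 1500),
                               "A", "g1", gm, genome), "flanking")
})

test_that("SNPs in overlapping genes yield one record per gene", {
  d <- withr::local_tempdir()
  seqc <- strrep("ACGT", 500)
  gff <- file.path(d, "two.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t101\t160\t.\t+\t.\tID=ga",
    "chr1\tt\tmRNA\t101\t160\t.\t+\t.\tID=ga.t1;Parent=ga",
    "chr1\tt\tCDS\t101\t160\t.\t+\t0\tParent=ga.t1",
    "chr1\tt\tgene\t141\t200\t.\t+\t.\tID=gb",
    "chr1\tt\tmRNA\t141\t200\t.\t+\t.\tID=gb.t1;Parent=gb",
    "chr1\tt\tCDS\t141\t200\t.\t+\t0\tParent=gb.t1"), gff)
  writeLines(c(">chr1", seqc), file.path(d, "two.fasta"))
  genome <- read_genome_fasta(file.path(d, "two.fasta"))
  gm <- read_gff3(gff, genome)
  asg <- assign_snp_to_genes(data.frame(scaffold = "chr1", pos = 150), gm)
  expect_equal(sort(asg$gene_id), c("ga", "gb"))
})

test_that("codon-local classification agrees with full-CDS translation diffs", {
  # oracle: substitute the allele into the whole spliced CDS, translate both
  # proteins with Biostrings, and diff - independent of the codon arithmetic
  sim <- simulate_popgen_dataset(sim_config(n_scaffolds = 2,
                                            scaffold_length = 8000,
                                            genes_per_scaffold = 4,
                                            seed = 21))
  d <- withr::local_tempdir()
  writeLines(sim$gff_lines, file.path(d, "sim.gff3"))
  gm <- read_gff3(file.path(d, "sim.gff3"), sim$genome)
  set.seed(22)
  checked <- 0L
  for (rep in 1:1000) {
    gi <- gm$genes[sample(nrow(gm$genes), 1), ]
    cds <- gm$features[gm$features$gene_id == gi$gene_id &
                         gm$features$type == "CDS", ]
    pos <- sample(unlist(Map(seq, cds$start, cds$end)), 1)
    ref <- as.character(Biostrings::subseq(sim$genome[[gi$scaffold]],
                                           pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_effect(gi$scaffold, pos, ref, alt, gi$gene_id, gm,
                           sim$genome)
    # oracle
    mut_genome <- sim$genome
    g1 <- Biostrings::DNAString(as.character(mut_genome[[gi$scaffold]]))
    Biostrings::subseq(g1, pos, pos) <- Biostrings::DNAString(alt)
    mut_genome[[gi$scaffold]] <- g1
    p_ref <- Biostrings::translate(
      Biostrings::DNAString(cds_sequence(gm, gi$gene_id, sim$genome)))
    p_mut <- Biostrings::translate(
      Biostrings::DNAString(cds_sequence(gm, gi$gene_id, mut_genome)))
    want <- if (as.character(p_ref) == as.character(p_mut))
      "synonymous" else "nonsynonymous"
    expect_equal(got, want,
                 info = sprintf("%s pos %d %s>%s", gi$gene_id, pos, ref, alt))
    checked <- checked + 1L
  }
  expect_equal(checked, 1000L)
})

test_that("Muller assignment needs 55% agreement, inclusive, order-invariant", {
  bh <- function(n_a, n_b, sc = "s1") {
    data.frame(scaffold = sc,
               gene = paste0(sc, "g", seq_len(n_a + n_b)),
               element = c(rep("A", n_a), rep("B", n_b)))
  }
  expect_equal(assign_muller(bh(6, 4))$element, "A")     # 60%
  expect_true(is.na(assign_muller(bh(5, 5))$element))    # 50%
  expect_equal(assign_muller(bh(11, 9))$element, "A")    # exactly 55%
  # invariant to row order and duplicates
  x <- bh(11, 9)
  shuffled <- x[sample(nrow(x)), ]
  dup <- rbind(x, x[1:5, ])
  expect_equal(assign_muller(shuffled)$element, "A")
  expect_equal(assign_muller(dup)$element, "A")
  expect_equal(assign_muller(dup)$n_genes, 20L)
})
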