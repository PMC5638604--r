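#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Defaults describe a
#' desk-scale two-population pooled-sequencing study shaped like the real
#' one: two pools at mean coverages 60 and 70 (the low- and high-latitude
#' pool coverages of the study), a handful of annotated scaffolds standing in
#' for chromosome arms, SNP density and allele-frequency spectrum tuned so
#' genome-wide nucleotide diversity lands near 0.002, a small fraction of
#' SNPs under spatially varying selection with a deterministic frequency
#' shift in population 1, and drift modelled as a single binomial resampling
#' step per population.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each scaffold in bp.
#' @param genes_per_scaffold gene models placed per scaffold.
#' @param coverage_mean length-2 vector of mean pool coverages (reads/site).
#' @param snp_density per-bp probability that a site is polymorphic.
#' @param frac_selected_snps fraction of SNPs given the selection shift.
#' @param selection_shift derived-allele frequency increase in population 1
#'   at selected SNPs (capped at 1).
#' @param drift_size binomial denominator of the drift step (smaller = more
#'   drift).
#' @param divergence per-bp substitution probability on the outgroup branch.
#' @param divergence_third_only restrict outgroup substitutions to third
#'   codon positions of genes (makes divergence mostly synonymous).
#' @param n_genes_mk genes in the MK generator.
#' @param mean_ps,mean_ds expected synonymous polymorphism/divergence counts
#'   per gene.
#' @param pn_ps_ratio expected Pn/Ps ratio under neutrality.
#' @param alpha_grid true alpha values cycled over MK genes.
#' @param n_expressed_genes ortholog pairs in the expression generator.
#' @param frac_de fraction of truly differentially expressed genes per
#'   species.
#' @param de_lfc_sigma standard deviation of true log2 fold-change effects.
#' @param shared_de_fraction fraction of species A's DE genes that are also
#'   DE (with concordant sign) in species B.
#' @param expr_noise_sigma log2-scale observation noise.
#' @param seed integer RNG seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_scaffolds = 4,
                       scaffold_length = 20000,
                       genes_per_scaffold = 6,
                       coverage_mean = c(60, 70),
                       snp_density = 0.006,
                       frac_selected_snps = 0.02,
                       selection_shift = 0.6,
                       drift_size = 200,
                       divergence = 0.05,
                       divergence_third_only = FALSE,
                       n_genes_mk = 500,
                       mean_ps = 8,
                       mean_ds = 12,
                       pn_ps_ratio = 0.25,
                       alpha_grid = c(0, 0.2, 0.5, 0.8),
                       n_expressed_genes = 3000,
                       frac_de = 0.05,
                       de_lfc_sigma = 3,
                       shared_de_fraction = 0.5,
                       expr_noise_sigma = 0.25,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$coverage_mean) != 2L)
    stop("coverage_mean must give a mean per pool (length 2)")
  fr <- c(cfg$frac_selected_snps, cfg$frac_de, cfg$shared_de_fraction,
          cfg$snp_density)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(cfg$alpha_grid >= 1)) stop("true alpha must be < 1")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# Fixed intron-containing gene layout used by the popgen generator:
# 5'UTR 100 bp, CDS exon 150 bp, intron 120 bp, CDS exon 150 bp, 3'UTR 100 bp
# (mirrored on the minus strand). CDS totals 300 bp, in frame.
gene_layout <- function(tx_start, strand) {
  u5 <- 100L; cds <- 150L; intr <- 120L; u3 <- 100L
  b <- tx_start
  segs <- data.frame(
    type = c("five_prime_UTR", "CDS", "CDS", "three_prime_UTR"),
    start = c(b, b + u5, b + u5 + cds + intr,
              b + u5 + cds + intr + cds),
    end = c(b + u5 - 1L, b + u5 + cds - 1L,
            b + u5 + cds + intr + cds - 1L,
            b + u5 + cds + intr + cds + u3 - 1L),
    stringsAsFactors = FALSE)
  if (strand == "-")
    segs$type <- rev(segs$type)
  segs
}

gff3_lines <- function(scaffold, gene_id, strand, segs) {
  tx_start <- min(segs$start); tx_end <- max(segs$end)
  mrna_id <- paste0(gene_id, ".t1")
  rows <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            scaffold, tx_start, tx_end, strand, gene_id),
    sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            scaffold, tx_start, tx_end, strand, mrna_id, gene_id))
  cds <- segs[segs$type == "CDS", ]
  cds <- cds[order(cds$start), ]
  # phase in transcription order; exon lengths are multiples of 3 here
  phase <- rep(0L, nrow(cds))
  exon_rows <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       scaffold, segs$start, segs$end, strand, mrna_id)
  other <- segs[segs$type != "CDS", ]
  feat_rows <- c(
    sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
            scaffold, cds$start, cds$end, strand, phase, mrna_id),
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
            scaffold, other$type, other$start, other$end, strand, mrna_id))
  c(rows, exon_rows, feat_rows)
}

# ancestral derived-allele frequencies from a neutral-SFS-like density
# (weight proportional to 1/x on a truncated grid)
rsfs_freq <- function(n, grid = seq(0.05, 0.95, by = 0.01)) {
  sample(grid, n, replace = TRUE, prob = 1 / grid)
}

#' Simulate a two-population pooled-sequencing dataset
#'
#' Generates a genome FASTA, gene models (GFF3), an outgroup FASTA, a
#' two-pool sync file of read counts at every site, and a ground-truth table.
#' Derived-allele ancestral frequencies are drawn from a 1/x density;
#' population frequencies arise from one binomial drift step each; a
#' configurable fraction of SNPs gets a deterministic extra shift in
#' population 1; coverage is Poisson per pool and read counts binomial in
#' the population frequency. The outgroup sequence carries the ancestral
#' allele plus independent divergence substitutions.
#'
#' @param cfg a [sim_config()].
#' @param dir when given, all files are written under it (`genome.fasta`,
#'   `outgroup.fasta`, `genes.gff3`, `counts.sync`, `truth_snps.tsv`,
#'   `manifest.json`).
#' @return A list with `genome`, `outgroup` (`DNAStringSet`), `gff_lines`,
#'   `sync`, `truth` (one row per SNP), `scaffold_lengths` and `config`.
#' @export
simulate_popgen_dataset <- function(cfg = sim_config(), dir = NULL) {
  old_seed <- set_local_seed(cfg$seed)
  on.exit(restore_seed(old_seed))
  scafs <- sprintf("scf%02d", seq_len(cfg$n_scaffolds))
  L <- cfg$scaffold_length
  genome_chr <- vapply(scafs, function(s) random_dna(L), character(1))
  # gene models: evenly spaced, alternating strand
  gff <- c("##gff-version 3")
  gene_tbl <- list()
  spacing <- floor(L / cfg$genes_per_scaffold)
  tx_len <- 620L
  if (spacing < tx_len + 200L)
    stop("scaffold_length too small for genes_per_scaffold")
  gi <- 0L
  for (s in seq_along(scafs)) {
    for (g in seq_len(cfg$genes_per_scaffold)) {
      gi <- gi + 1L
      gene_id <- sprintf("gene%04d", gi)
      strand <- if (g %% 2L == 0L) "-" else "+"
      tx_start <- (g - 1L) * spacing + 101L
      segs <- gene_layout(tx_start, strand)
      gff <- c(gff, gff3_lines(scafs[s], gene_id, strand, segs))
      gene_tbl[[gi]] <- data.frame(gene_id = gene_id, scaffold = scafs[s],
                                   strand = strand, tx_start = tx_start,
                                   tx_end = tx_start + tx_len - 1L,
                                   stringsAsFactors = FALSE)
    }
  }
  gene_tbl <- do.call(rbind, gene_tbl)
  # polymorphic sites
  truth <- list()
  sync_sites <- list()
  cnt1 <- cnt2 <- list()
  third_pos <- third_position_mask(gene_tbl, scafs, L)
  for (s in seq_along(scafs)) {
    seq_chars <- strsplit(genome_chr[s], "")[[1]]
    is_snp <- stats::runif(L) < cfg$snp_density
    snp_pos <- which(is_snp)
    n_snp <- length(snp_pos)
    anc <- seq_chars[snp_pos]
    der <- vapply(anc, function(b) sample(setdiff(BASES, b), 1L),
                  character(1))
    x <- rsfs_freq(n_snp)
    p1 <- stats::rbinom(n_snp, cfg$drift_size, x) / cfg$drift_size
    p2 <- stats::rbinom(n_snp, cfg$drift_size, x) / cfg$drift_size
    sel <- stats::runif(n_snp) < cfg$frac_selected_snps
    p1[sel] <- pmin(1, p1[sel] + cfg$selection_shift)
    # read counts at every site of the scaffold
    cov1 <- stats::rpois(L, cfg$coverage_mean[1])
    cov2 <- stats::rpois(L, cfg$coverage_mean[2])
    d1 <- d2 <- integer(L)
    d1[snp_pos] <- stats::rbinom(n_snp, cov1[snp_pos], p1)
    d2[snp_pos] <- stats::rbinom(n_snp, cov2[snp_pos], p2)
    ref_allele <- seq_chars
    alt_allele <- rep(NA_character_, L)
    alt_allele[snp_pos] <- der
    m1 <- counts_matrix(ref_allele, alt_allele, cov1, d1)
    m2 <- counts_matrix(ref_allele, alt_allele, cov2, d2)
    sync_sites[[s]] <- data.frame(scaffold = scafs[s], pos = seq_len(L),
                                  ref = ref_allele, stringsAsFactors = FALSE)
    cnt1[[s]] <- m1; cnt2[[s]] <- m2
    truth[[s]] <- data.frame(
      scaffold = scafs[s], pos = snp_pos, ancestral = anc, derived = der,
      freq_anc = x, p1 = p1, p2 = p2, selected = sel,
      stringsAsFactors = FALSE)
  }
  sync <- new_sync(do.call(rbind, sync_sites),
                   list(do.call(rbind, cnt1), do.call(rbind, cnt2)))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  # outgroup: ancestral alleles plus divergence substitutions
  out_chr <- genome_chr
  for (s in seq_along(scafs)) {
    chars <- strsplit(out_chr[s], "")[[1]]
    eligible <- if (cfg$divergence_third_only)
      which(third_pos[[s]]) else seq_len(L)
    nsub <- stats::rbinom(1L, length(eligible), cfg$divergence)
    at <- sample(eligible, nsub)
    chars[at] <- vapply(chars[at], function(b)
      sample(setdiff(BASES, b), 1L), character(1))
    out_chr[s] <- paste(chars, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(genome_chr)
  names(genome) <- scafs
  outgroup <- Biostrings::DNAStringSet(out_chr)
  names(outgroup) <- scafs
  res <- list(genome = genome, outgroup = outgroup, gff_lines = gff,
              sync = sync, truth = truth,
              scaffold_lengths = stats::setNames(rep(L, length(scafs)),
                                                 scafs),
              genes = gene_tbl, config = cfg)
  if (!is.null(dir)) write_popgen_dataset(res, dir)
  res
}

# per-scaffold logical mask of third codon positions (genomic coordinates)
third_position_mask <- function(gene_tbl, scafs, L) {
  masks <- lapply(scafs, function(s) logical(L))
  names(masks) <- scafs
  for (i in seq_len(nrow(gene_tbl))) {
    segs <- gene_layout(gene_tbl$tx_start[i], gene_tbl$strand[i])
    cds <- segs[segs$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    pos <- unlist(lapply(seq_len(nrow(cds)), function(j)
      cds$start[j]:cds$end[j]))
    if (gene_tbl$strand[i] == "-") pos <- rev(pos)
    third <- pos[seq_along(pos) %% 3L == 0L]
    masks[[gene_tbl$scaffold[i]]][third] <- TRUE
  }
  masks
}

counts_matrix <- function(ref, alt, cov, derived) {
  n <- length(ref)
  m <- matrix(0L, n, 6L, dimnames = list(NULL, SYNC_BASES))
  ref_n <- cov - derived
  m[cbind(seq_len(n), match(ref, SYNC_BASES))] <- ref_n
  has_alt <- !is.na(alt)
  m[cbind(which(has_alt), match(alt[has_alt], SYNC_BASES))] <-
    derived[has_alt]
  m
}

write_popgen_dataset <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(res$genome, file.path(dir, "genome.fasta"))
  Biostrings::writeXStringSet(res$outgroup, file.path(dir, "outgroup.fasta"))
  writeLines(res$gff_lines, file.path(dir, "genes.gff3"))
  write_sync(res$sync, file.path(dir, "counts.sync"))
  write_tsv(res$truth, file.path(dir, "truth_snps.tsv"))
  write_manifest(dir, res$config, stage = "simulate")
  invisible(dir)
}

#' Simulate per-gene McDonald-Kreitman data with known true alpha
#'
#' For each gene a true alpha is taken from `alpha_grid` (cycled), the
#' expected counts follow E\[Ps\] = `mean_ps`, E\[Pn\] = `pn_ps_ratio` *
#' `mean_ps`, E\[Ds\] = `mean_ds` and E\[Dn\] = (E\[Ds\] E\[Pn\] / E\[Ps\]) /
#' (1 - alpha), and realized counts are independent Poisson draws. With
#' `emit_alignments = TRUE` each gene's realized counts are also planted as
#' substitutions into a generated in-frame codon alignment triplet
#' (allele 1, allele 2, outgroup) that [build_mk_table()] recovers exactly.
#'
#' @param cfg a [sim_config()].
#' @param emit_alignments also return planted codon alignments.
#' @param dir when given, writes `mk_counts.tsv` (+ `mk_alignments.fasta`)
#'   and a manifest under it.
#' @return A list with `counts` (gene, true_alpha, Dn, Ds, Pn, Ps),
#'   `alignments` (named list of character triplets, or `NULL`), and
#'   `config`.
#' @export
simulate_mk_dataset <- function(cfg = sim_config(), emit_alignments = FALSE,
                                dir = NULL) {
  old_seed <- set_local_seed(cfg$seed + 1L)
  on.exit(restore_seed(old_seed))
  n <- cfg$n_genes_mk
  true_alpha <- rep_len(cfg$alpha_grid, n)
  e_ps <- cfg$mean_ps
  e_pn <- cfg$pn_ps_ratio * e_ps
  e_ds <- cfg$mean_ds
  e_dn <- (e_ds * e_pn / e_ps) / (1 - true_alpha)
  counts <- data.frame(
    gene = sprintf("mk%05d", seq_len(n)),
    true_alpha = true_alpha,
    Dn = stats::rpois(n, e_dn), Ds = stats::rpois(n, e_ds),
    Pn = stats::rpois(n, e_pn), Ps = stats::rpois(n, e_ps),
    stringsAsFactors = FALSE)
  alignments <- NULL
  if (emit_alignments) {
    alignments <- lapply(seq_len(n), function(i)
      plant_mk_alignment(counts$Dn[i], counts$Ds[i], counts$Pn[i],
                         counts$Ps[i]))
    names(alignments) <- counts$gene
  }
  res <- list(counts = counts, alignments = alignments, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(counts, file.path(dir, "mk_counts.tsv"))
    if (emit_alignments) {
      fa <- unlist(lapply(names(alignments), function(g) {
        a <- alignments[[g]]
        c(sprintf(">%s_allele1", g), a[1],
          sprintf(">%s_allele2", g), a[2],
          sprintf(">%s_outgroup", g), a[3])
      }))
      writeLines(fa, file.path(dir, "mk_alignments.fasta"))
    }
    write_manifest(dir, cfg, stage = "simulate_mk")
  }
  res
}

# codon pairs differing by one base: synonymous and nonsynonymous templates
SYN_PAIR <- c(ref = "CTG", alt = "CTA")   # Leu -> Leu
NONSYN_PAIR <- c(ref = "ATG", alt = "ATA") # Met -> Ile
FILLER_CODON <- "GCC"

# One codon per planted change; the reference codon context is identical in
# both focal alleles wherever a fixed difference is planted.
plant_mk_alignment <- function(Dn, Ds, Pn, Ps, n_filler = 10L) {
  kinds <- c(rep("Dn", Dn), rep("Ds", Ds), rep("Pn", Pn), rep("Ps", Ps),
             rep("fill", n_filler))
  f1 <- f2 <- og <- character(length(kinds))
  for (i in seq_along(kinds)) {
    k <- kinds[i]
    if (k == "fill") {
      f1[i] <- f2[i] <- og[i] <- FILLER_CODON
    } else if (k == "Dn") {
      f1[i] <- f2[i] <- NONSYN_PAIR["ref"]; og[i] <- NONSYN_PAIR["alt"]
    } else if (k == "Ds") {
      f1[i] <- f2[i] <- SYN_PAIR["ref"]; og[i] <- SYN_PAIR["alt"]
    } else if (k == "Pn") {
      f1[i] <- NONSYN_PAIR["ref"]; f2[i] <- NONSYN_PAIR["alt"]
      og[i] <- NONSYN_PAIR["ref"]
    } else {
      f1[i] <- SYN_PAIR["ref"]; f2[i] <- SYN_PAIR["alt"]
      og[i] <- SYN_PAIR["ref"]
    }
  }
  c(paste(f1, collapse = ""), paste(f2, collapse = ""),
    paste(og, collapse = ""))
}

#' Simulate two-species FPKM tables with controllable shared DE
#'
#' Ortholog pairs get a shared baseline expression level (log2 FPKM normal);
#' each species has a fraction `frac_de` of truly differentially expressed
#' genes with log2 effects ~ N(0, `de_lfc_sigma`); a fraction
#' `shared_de_fraction` of species A's DE genes are also DE in species B
#' with a concordant sign. Log-normal observation noise is added per sample.
#'
#' @param cfg a [sim_config()].
#' @param dir when given, writes `fpkm_a.tsv`, `fpkm_b.tsv`,
#'   `orthologs.tsv`, `truth_expression.tsv` and a manifest.
#' @return A list with `fpkm_a`, `fpkm_b` (gene, pop1, pop2),
#'   `ortholog_map`, `truth` and `config`.
#' @export
simulate_expression_dataset <- function(cfg = sim_config(), dir = NULL) {
  old_seed <- set_local_seed(cfg$seed + 2L)
  on.exit(restore_seed(old_seed))
  n <- cfg$n_expressed_genes
  ga <- sprintf("ga%05d", seq_len(n))
  gb <- sprintf("gb%05d", seq_len(n))
  base <- stats::rnorm(n, mean = 4, sd = 1.5)
  n_de <- round(cfg$frac_de * n)
  de_a <- sample.int(n, n_de)
  n_shared <- round(cfg$shared_de_fraction * n_de)
  shared <- sample(de_a, n_shared)
  # the non-deliberately-shared part of B's DE set is drawn independently of
  # A's (chance overlap allowed), so shared_de_fraction = 0 is a true
  # independence null
  de_b <- c(shared, sample(setdiff(seq_len(n), shared), n_de - n_shared))
  lfc_a <- lfc_b <- numeric(n)
  lfc_a[de_a] <- stats::rnorm(n_de, 0, cfg$de_lfc_sigma)
  lfc_b[de_b] <- stats::rnorm(n_de, 0, cfg$de_lfc_sigma)
  lfc_b[shared] <- sign(lfc_a[shared]) * abs(lfc_b[shared])
  noisy <- function(l2) 2^(l2 + stats::rnorm(n, 0, cfg$expr_noise_sigma))
  fpkm_a <- data.frame(gene = ga,
                       pop1 = noisy(base + lfc_a / 2),
                       pop2 = noisy(base - lfc_a / 2),
                       stringsAsFactors = FALSE)
  fpkm_b <- data.frame(gene = gb,
                       pop1 = noisy(base + lfc_b / 2),
                       pop2 = noisy(base - lfc_b / 2),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_a = ga, gene_b = gb,
                      de_a = seq_len(n) %in% de_a,
                      de_b = seq_len(n) %in% de_b,
                      shared_de = seq_len(n) %in% shared,
                      lfc_a_true = lfc_a, lfc_b_true = lfc_b,
                      stringsAsFactors = FALSE)
  map <- data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
  res <- list(fpkm_a = fpkm_a, fpkm_b = fpkm_b, ortholog_map = map,
              truth = truth, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(fpkm_a, file.path(dir, "fpkm_a.tsv"))
    write_tsv(fpkm_b, file.path(dir, "fpkm_b.tsv"))
    write_tsv(map, file.path(dir, "orthologs.tsv"))
    write_tsv(truth, file.path(dir, "truth_expression.tsv"))
    write_manifest(dir, cfg, stage = "simulate_expression")
  }
  res
}
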