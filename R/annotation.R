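#' Assign SNPs to gene regions
#'
#' A SNP belongs to a gene's region when it lies within the transcript span
#' extended by `flank_bp` (default 1000 bp, boundary inclusive) on both
#' sides. A SNP inside several overlapping gene regions yields one record per
#' gene; SNPs outside every gene region yield none.
#'
#' @param snps data.frame with `scaffold` and `pos` columns.
#' @param models a `"gene_models"` object from [read_gff3()].
#' @param cfg an [analysis_config()] (supplies `flank_bp`).
#' @return data.frame with `snp_idx` (row index into `snps`) and `gene_id`.
#' @export
assign_snp_to_genes <- function(snps, models, cfg = analysis_config()) {
  g <- models$genes
  out <- vector("list", length(unique(g$scaffold)))
  k <- 0L
  for (sc in unique(g$scaffold)) {
    gi <- g[g$scaffold == sc, ]
    si <- which(snps$scaffold == sc)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(snps$pos[si], width = 1L),
      IRanges::IRanges(pmax(1L, gi$tx_start - cfg$flank_bp),
                       gi$tx_end + cfg$flank_bp))
    if (!length(hits)) next
    k <- k + 1L
    out[[k]] <- data.frame(
      snp_idx = si[S4Vectors::queryHits(hits)],
      gene_id = gi$gene_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(snp_idx = integer(), gene_id = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$snp_idx, res$gene_id), , drop = FALSE]
}

#' Classify the effect of a SNP on a gene
#'
#' Feature classes are assigned with priority CDS > UTR > intron > flanking.
#' For coding SNPs the alternate allele is substituted into the reference
#' codon (the other two positions keep their reference state; minus-strand
#' genes are handled in transcript orientation) and translated with the
#' standard nuclear code: `synonymous` when the amino acid is unchanged,
#' `nonsynonymous` otherwise. Codons containing an N are `undetermined` and
#' excluded downstream.
#'
#' @param scaffold,pos,ref,alt the SNP (1-based genomic position, genomic
#'   strand alleles).
#' @param gene_id gene to classify against (its region must contain the SNP).
#' @param models a `"gene_models"` object.
#' @param genome `DNAStringSet` of scaffold sequences.
#' @param cfg an [analysis_config()].
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"intronic"`, `"UTR5"`,
#'   `"UTR3"`, `"flanking"`, `"undetermined"`.
#' @export
classify_effect <- function(scaffold, pos, ref, alt, gene_id, models, genome,
                            cfg = analysis_config()) {
  gi <- models$genes[models$genes$gene_id == gene_id, ]
  if (nrow(gi) != 1L) stop("unknown gene: ", gene_id)
  if (gi$scaffold != scaffold) stop("SNP scaffold does not match gene")
  fe <- models$features[models$features$gene_id == gene_id, ]
  scaf <- genome[[scaffold]]
  genome_base <- toupper(as.character(Biostrings::subseq(scaf, pos, pos)))
  if (genome_base != toupper(ref))
    stop(sprintf("reference mismatch at %s:%d (FASTA %s, SNP ref %s)",
                 scaffold, pos, genome_base, ref))
  inside <- function(type) {
    f <- fe[fe$type == type, , drop = FALSE]
    nrow(f) > 0L && any(pos >= f$start & pos <= f$end)
  }
  if (inside("CDS")) {
    cds <- fe[fe$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    # genomic -> CDS coordinate (transcription order)
    before <- cds$end < pos
    within <- which(pos >= cds$start & pos <= cds$end)
    offset_plus <- sum(cds$end[before] - cds$start[before] + 1L) +
      (pos - cds$start[within] + 1L)
    total <- sum(cds$end - cds$start + 1L)
    cpos <- if (gi$strand == "+") offset_plus else total - offset_plus + 1L
    seq <- cds_seq_raw(cds, scaf, gi$strand)
    first <- if (gi$strand == "-") which.max(cds$end) else which.min(cds$start)
    ph <- cds$phase[first]
    cpos <- cpos - ph
    if (cpos < 1L || cpos > (total - ph) - (total - ph) %% 3L)
      return("undetermined")  # phase-trimmed or trailing partial codon
    seq <- substr(seq, ph + 1L, nchar(seq))
    codon_i <- (cpos - 1L) %/% 3L
    in_codon <- cpos - codon_i * 3L
    codon <- substr(seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_tx <- if (gi$strand == "+") toupper(alt) else comp_base(toupper(alt))
    mutant <- codon
    substr(mutant, in_codon, in_codon) <- alt_tx
    if (grepl("[^ACGT]", codon) || grepl("[^ACGT]", mutant))
      return("undetermined")
    if (translate_codon(codon) == translate_codon(mutant))
      "synonymous" else "nonsynonymous"
  } else if (inside("five_prime_UTR")) {
    "UTR5"
  } else if (inside("three_prime_UTR")) {
    "UTR3"
  } else if (pos >= gi$tx_start && pos <= gi$tx_end) {
    "intronic"
  } else {
    "flanking"
  }
}

cds_seq_raw <- function(cds, scaf, strand) {
  segs <- vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(scaf, cds$start[i], cds$end[i])),
    character(1))
  seq <- paste(segs, collapse = "")
  if (strand == "-")
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  toupper(seq)
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A",
                           N = "N")[b]

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate SNPs with gene assignments and effect classes
#'
#' Combines [assign_snp_to_genes()] and [classify_effect()] over a SNP table.
#'
#' @param snps data.frame with `scaffold`, `pos`, `ref` and alternate allele
#'   column `alt` (or `minor`).
#' @param models a `"gene_models"` object.
#' @param genome `DNAStringSet`.
#' @param cfg an [analysis_config()].
#' @return data.frame with `snp_idx`, `gene_id` and `effect`.
#' @export
annotate_snps <- function(snps, models, genome, cfg = analysis_config()) {
  alt <- if ("alt" %in% names(snps)) snps$alt else snps$minor
  asg <- assign_snp_to_genes(snps, models, cfg)
  if (!nrow(asg)) {
    asg$effect <- character(0)
    return(asg)
  }
  asg$effect <- vapply(seq_len(nrow(asg)), function(i) {
    j <- asg$snp_idx[i]
    classify_effect(snps$scaffold[j], snps$pos[j], snps$ref[j], alt[j],
                    asg$gene_id[i], models, genome, cfg)
  }, character(1))
  asg
}

#' Assign scaffolds to Muller elements
#'
#' A scaffold is assigned to a Muller element when at least 55% of its
#' annotated genes have their best alignment to that single element
#' (boundary inclusive); otherwise it is left unassigned. Duplicate
#' (scaffold, gene) rows are collapsed and gene order is irrelevant.
#'
#' @param best_hits data.frame with columns `scaffold`, `gene`, `element`.
#' @param threshold minimum fraction of genes agreeing on one element.
#' @return data.frame with `scaffold`, `element` (`NA` = unassigned),
#'   `n_genes` and `top_fraction`.
#' @export
assign_muller <- function(best_hits, threshold = 0.55) {
  stopifnot(all(c("scaffold", "gene", "element") %in% names(best_hits)))
  bh <- unique(best_hits[c("scaffold", "gene", "element")])
  scs <- unique(bh$scaffold)
  res <- lapply(scs, function(sc) {
    sub <- bh[bh$scaffold == sc, ]
    tab <- sort(table(sub$element), decreasing = TRUE)
    frac <- as.numeric(tab[1]) / nrow(sub)
    data.frame(scaffold = sc,
               element = if (frac >= threshold) names(tab)[1]
                         else NA_character_,
               n_genes = nrow(sub), top_fraction = frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
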