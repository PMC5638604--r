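#' Read a genome FASTA
#'
#' @param path FASTA file of scaffold sequences.
#' @return A [Biostrings::DNAStringSet] named by scaffold id (first word of
#'   the header).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read gene models from GFF3
#'
#' Builds one gene model per gene from a GFF3 file with gene/mRNA/exon/CDS/UTR
#' features. When a gene has several mRNA isoforms the one with the longest
#' total CDS is kept. Coordinates are 1-based inclusive throughout. Genes
#' whose CDS length is not a multiple of 3 after the phase of the first coding
#' segment is trimmed are flagged `untranslatable` with a warning.
#'
#' @param path GFF3 file.
#' @param genome optional `DNAStringSet`; when given, every gene's scaffold
#'   must be present in it.
#' @return An object of class `"gene_models"`: a list with `genes`, a
#'   data.frame (`gene_id`, `scaffold`, `strand`, `tx_start`, `tx_end`,
#'   `cds_len`, `untranslatable`), and `features`, a data.frame of the kept
#'   transcript's parts (`gene_id`, `type`, `start`, `end`, `phase`).
#' @export
read_gff3 <- function(path, genome = NULL) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  genes <- g[g$type == "gene", ]
  mrnas <- g[g$type == "mRNA", ]
  parts <- g[g$type %in% c("exon", "CDS", "five_prime_UTR",
                           "three_prime_UTR"), ]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  if (!is.null(genome)) {
    missing <- setdiff(unique(as.character(genes$seqid)), names(genome))
    if (length(missing))
      stop("scaffold(s) in GFF3 absent from FASTA: ",
           paste(missing, collapse = ", "))
  }
  cds_len_of <- function(tx_id) {
    p <- parts[parts$Parent == tx_id & parts$type == "CDS", ]
    sum(p$end - p$start + 1L)
  }
  keep_feats <- vector("list", nrow(genes))
  info <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas[mrnas$Parent == gid, ]
    if (nrow(tx) == 0L) stop("gene without mRNA: ", gid)
    lens <- vapply(tx$ID, cds_len_of, numeric(1))
    best <- tx[which.max(lens), ]
    fp <- parts[parts$Parent == best$ID, ]
    fp <- fp[order(fp$start), ]
    cds <- fp[fp$type == "CDS", ]
    phase0 <- if (nrow(cds)) {
      first <- if (best$strand == "-") which.max(cds$end) else which.min(cds$start)
      ph <- suppressWarnings(as.integer(as.character(cds$phase[first])))
      if (is.na(ph)) 0L else ph
    } else 0L
    cds_len <- sum(cds$end - cds$start + 1L)
    untr <- cds_len > 0L && ((cds_len - phase0) %% 3L != 0L)
    if (untr)
      warning("gene ", gid, ": CDS length ", cds_len,
              " not divisible by 3 after phase; flagged untranslatable")
    info[[i]] <- data.frame(
      gene_id = gid, scaffold = as.character(best$seqid),
      strand = as.character(best$strand),
      tx_start = best$start, tx_end = best$end,
      cds_len = cds_len, untranslatable = untr,
      stringsAsFactors = FALSE)
    keep_feats[[i]] <- data.frame(
      gene_id = gid, type = as.character(fp$type),
      start = fp$start, end = fp$end,
      phase = {
        ph <- suppressWarnings(as.integer(as.character(fp$phase)))
        ifelse(is.na(ph), 0L, ph)
      },
      stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, info),
                 features = do.call(rbind, keep_feats)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d scaffold(s)\n",
              nrow(x$genes), length(unique(x$genes$scaffold))))
  invisible(x)
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the CDS intervals in transcription order, reverse-complements
#' minus-strand genes, and trims the phase of the first coding segment.
#'
#' @param models a `"gene_models"` object.
#' @param gene_id gene to extract.
#' @param genome `DNAStringSet` holding the gene's scaffold.
#' @return The in-frame CDS as a character string.
#' @export
cds_sequence <- function(models, gene_id, genome) {
  gi <- models$genes[models$genes$gene_id == gene_id, ]
  if (nrow(gi) != 1L) stop("unknown gene: ", gene_id)
  cds <- models$features[models$features$gene_id == gene_id &
                           models$features$type == "CDS", ]
  cds <- cds[order(cds$start), ]
  scaf <- genome[[gi$scaffold]]
  segs <- vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(scaf, cds$start[i], cds$end[i])),
    character(1))
  seq <- paste(segs, collapse = "")
  if (gi$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  first <- if (gi$strand == "-") which.max(cds$end) else which.min(cds$start)
  ph <- cds$phase[first]
  if (ph > 0L) seq <- substr(seq, ph + 1L, nchar(seq))
  seq
}
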