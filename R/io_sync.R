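#' Read pooled allele counts in sync format
#'
#' Parses the tab-delimited "sync" format used by pooled-sequencing pipelines:
#' one line per site with scaffold, 1-based position, reference base, then one
#' `A:T:C:G:N:del` count sextet per population pool. All counts are read
#' exactly as written; no filtering is applied here.
#'
#' @param path path to a sync file.
#' @param n_pools expected number of pools; inferred from the first line when
#'   `NULL`, and enforced on every line.
#' @return An object of class `"sync"`: a list with `sites`, a data.frame of
#'   `scaffold`, `pos`, `ref`, and `counts`, a list of one integer matrix per
#'   pool (`n_sites` x 6, columns `A,T,C,G,N,del`).
#' @details Positions must be strictly increasing within each scaffold;
#'   malformed sextets, non-integer counts or a wrong column count raise an
#'   error naming the offending line. An empty file yields zero sites.
#' @examples
#' f <- tempfile(fileext = ".sync")
#' writeLines("scf1\t10\tA\t18:0:2:0:0:0\t20:0:0:0:0:0", f)
#' s <- read_sync(f)
#' s$counts[[1]]
#' @export
read_sync <- function(path, n_pools = NULL) {
  if (!file.exists(path)) stop("sync file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_sync(
      data.frame(scaffold = character(), pos = integer(), ref = character(),
                 stringsAsFactors = FALSE),
      list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (is.null(n_pools)) n_pools <- nf[1] - 3L
  if (n_pools < 1L) stop("sync line 1: fewer than 4 columns")
  bad <- which(nf != 3L + n_pools)
  if (length(bad))
    stop(sprintf("sync line %d: expected %d columns, found %d",
                 bad[1], 3L + n_pools, nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = 3L + n_pools, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1L))
    stop(sprintf("sync line %d: position is not a positive integer",
                 which(is.na(pos) | pos < 1L)[1]))
  sites <- data.frame(scaffold = m[, 1], pos = pos, ref = m[, 3],
                      stringsAsFactors = FALSE)
  # strictly increasing positions within a scaffold, in file order
  same <- sites$scaffold[-1] == sites$scaffold[-nrow(sites)]
  nondecr <- diff(sites$pos) > 0L
  viol <- which(same & !nondecr)
  if (length(viol))
    stop(sprintf("sync line %d: positions not strictly increasing on %s",
                 viol[1] + 1L, sites$scaffold[viol[1] + 1L]))
  counts <- vector("list", n_pools)
  for (j in seq_len(n_pools)) {
    sx <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    bad <- which(lengths(sx) != 6L)
    if (length(bad))
      stop(sprintf("sync line %d: count field '%s' is not a 6-part sextet",
                   bad[1], m[bad[1], 3L + j]))
    v <- suppressWarnings(as.integer(unlist(sx)))
    if (anyNA(v) || any(v < 0L)) {
      row <- ceiling(which(is.na(v) | v < 0L)[1] / 6)
      stop(sprintf("sync line %d: non-integer or negative count in '%s'",
                   row, m[row, 3L + j]))
    }
    counts[[j]] <- matrix(v, ncol = 6L, byrow = TRUE,
                          dimnames = list(NULL, SYNC_BASES))
  }
  new_sync(sites, counts)
}

SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

new_sync <- function(sites, counts) {
  structure(list(sites = sites, counts = counts,
                 n_pools = length(counts)), class = "sync")
}

#' Write pooled allele counts in sync format
#'
#' @param sync a `"sync"` object as returned by [read_sync()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  stopifnot(inherits(sync, "sync"))
  sextets <- lapply(sync$counts, function(m)
    apply(m, 1L, paste, collapse = ":"))
  n <- nrow(sync$sites)
  cols <- c(list(sync$sites$scaffold, sync$sites$pos, sync$sites$ref), sextets)
  lines <- if (n == 0L) character() else do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync: %d sites on %d scaffold(s), %d pools\n",
              nrow(x$sites), length(unique(x$sites$scaffold)), x$n_pools))
  invisible(x)
}

#' Estimate genome size from k-mer statistics
#'
#' Applies the standard k-mer identity G = Kmer_num / Kmer_depth, where
#' Kmer_num is the total number of k-mers over all reads and Kmer_depth the
#' modal (average) k-mer depth.
#'
#' @param kmer_num total k-mer count (> 0).
#' @param kmer_depth modal/average k-mer depth (> 0).
#' @return A list with `kmer_num`, `kmer_depth` and `size_bp`.
#' @examples
#' estimate_genome_size(1e6, 10)$size_bp  # 1e5
#' @export
estimate_genome_size <- function(kmer_num, kmer_depth) {
  if (!is.numeric(kmer_num) || !is.numeric(kmer_depth) ||
      kmer_num <= 0 || kmer_depth <= 0)
    stop("kmer_num and kmer_depth must both be positive")
  list(kmer_num = kmer_num, kmer_depth = kmer_depth,
       size_bp = kmer_num / kmer_depth)
}

# Small TSV helpers shared by the pipeline stages: plain tab-separated files,
# no quoting, NA written as "NA", exact round-trip of field values and order.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
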