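#' Expected heterozygosity of one pooled sample at one site
#'
#' Pooled-read estimator of per-site nucleotide diversity: with coverage
#' c = sum of base-call counts and allele read fractions c_a/c,
#' H = (c/(c-1)) * (1 - sum_a (c_a/c)^2). The c/(c-1) factor removes the
#' downward bias of the plug-in sum of squared frequencies under binomial
#' read sampling. N and deletion calls are not counts of bases and must be
#' excluded before calling.
#'
#' @param counts non-negative allele read counts (any number of alleles).
#' @return The corrected heterozygosity; 0 for a monomorphic site.
#' @examples
#' site_heterozygosity(c(10, 10))  # (20/19) * 0.5
#' @export
site_heterozygosity <- function(counts) {
  c_tot <- sum(counts)
  if (c_tot < 2) stop("site coverage must be at least 2")
  (c_tot / (c_tot - 1)) * (1 - sum((counts / c_tot)^2))
}

# vectorised two-allele version: a, b are count vectors of allele 1 / allele 2
het2 <- function(a, b) {
  c_tot <- a + b
  (c_tot / (c_tot - 1)) * (1 - (a / c_tot)^2 - (b / c_tot)^2)
}

#' Per-SNP F_ST between two pools
#'
#' F_ST = (pi_total - pi_within) / pi_total where pi_within is the unweighted
#' mean of the two pools' site heterozygosities and pi_total the
#' heterozygosity of the pooled (summed) counts. Negative values are retained;
#' sites monomorphic in the combined sample are undefined (`NA`). Because the
#' small-sample correction factor c/(c-1) is evaluated at the combined
#' coverage for pi_total but at each pool's coverage for pi_within, two pools
#' with identical counts give a slightly negative value of order -1/(2c)
#' rather than exactly zero; the bias vanishes as coverage grows.
#'
#' @param counts1,counts2 allele read counts for the same two alleles in each
#'   pool (length-2 vectors).
#' @return F_ST in (-Inf, 1], or `NA` when pi_total is zero.
#' @examples
#' snp_fst(c(20, 0), c(0, 20))  # 1: fixed difference
#' snp_fst(c(15, 5), c(5, 15))
#' @export
snp_fst <- function(counts1, counts2) {
  stopifnot(length(counts1) == 2L, length(counts2) == 2L)
  pi_t <- site_heterozygosity(counts1 + counts2)
  if (pi_t == 0) return(NA_real_)
  pi_w <- (site_heterozygosity(counts1) + site_heterozygosity(counts2)) / 2
  (pi_t - pi_w) / pi_t
}

snp_fst_vec <- function(a1, b1, a2, b2) {
  pi_t <- het2(a1 + a2, b1 + b2)
  pi_w <- (het2(a1, b1) + het2(a2, b2)) / 2
  out <- (pi_t - pi_w) / pi_t
  out[pi_t == 0] <- NA_real_
  out
}

#' Classify one pooled site
#'
#' Applies the site filters of the differentiation scan to one site's count
#' sextets. Coverage counts base calls only (A/C/G/T; N and deletion calls are
#' ignored). A site is rejected if any pool is below the coverage minimum;
#' kept as `monomorphic` if a single allele is observed; rejected as
#' `triallelic` if three or more alleles have non-zero combined counts; and
#' kept as a SNP only when the combined count of the rarer allele reaches
#' `min_alt_observations_popgen`.
#'
#' @param pools list (one element per pool) of count sextets named
#'   `A,T,C,G,N,del`, or a matrix with those columns.
#' @param cfg an [analysis_config()].
#' @return A list with `status` (one of `"snp"`, `"monomorphic"`,
#'   `"low_coverage"`, `"min_alt"`, `"triallelic"`) and, for SNPs, `major`,
#'   `minor` alleles and the per-pool count matrix.
#' @export
filter_site <- function(pools, cfg = analysis_config()) {
  if (is.list(pools)) pools <- do.call(rbind, pools)
  colnames(pools) <- SYNC_BASES[seq_len(ncol(pools))]
  bases <- pools[, c("A", "C", "G", "T"), drop = FALSE]
  cov <- rowSums(bases)
  if (any(cov < cfg$min_site_coverage))
    return(list(status = "low_coverage"))
  tot <- colSums(bases)
  seen <- which(tot > 0L)
  if (length(seen) <= 1L) return(list(status = "monomorphic"))
  if (length(seen) > 2L) return(list(status = "triallelic"))
  ord <- seen[order(-tot[seen], names(tot)[seen])]
  major <- names(tot)[ord[1]]
  minor <- names(tot)[ord[2]]
  if (tot[minor] < cfg$min_alt_observations_popgen)
    return(list(status = "min_alt"))
  list(status = "snp", major = major, minor = minor,
       counts = bases[, c(major, minor), drop = FALSE])
}

#' Site filtering and per-SNP F_ST over a whole dataset
#'
#' Vectorised application of [filter_site()] and [snp_fst()] to every site of
#' a two-pool sync dataset.
#'
#' @param sync a `"sync"` object with exactly 2 pools.
#' @param cfg an [analysis_config()].
#' @return A list with `status`, a factor per site, and `snps`, a data.frame
#'   of SNP records: scaffold, pos, ref, major/minor allele, per-pool counts
#'   (`maj1,min1,maj2,min2`), minor-allele frequencies `p1`, `p2`, and `fst`.
#' @export
classify_sites <- function(sync, cfg = analysis_config()) {
  stopifnot(inherits(sync, "sync"), sync$n_pools == 2L)
  b1 <- sync$counts[[1]][, c("A", "C", "G", "T"), drop = FALSE]
  b2 <- sync$counts[[2]][, c("A", "C", "G", "T"), drop = FALSE]
  cov1 <- rowSums(b1); cov2 <- rowSums(b2)
  tot <- b1 + b2
  n_alleles <- rowSums(tot > 0L)
  status <- rep("monomorphic", nrow(tot))
  status[n_alleles > 2L] <- "triallelic"
  low <- cov1 < cfg$min_site_coverage | cov2 < cfg$min_site_coverage
  # combined major/minor via ranking within each row
  is_bi <- n_alleles == 2L & !low
  status[low] <- "low_coverage"
  maj <- min <- rep(NA_character_, nrow(tot))
  if (any(is_bi)) {
    sub <- tot[is_bi, , drop = FALSE]
    # for each biallelic row find the two non-zero columns
    idx <- which(is_bi)
    nz <- apply(sub, 1L, function(r) which(r > 0L))
    a1 <- nz[1, ]; a2 <- nz[2, ]
    c1 <- sub[cbind(seq_len(nrow(sub)), a1)]
    c2 <- sub[cbind(seq_len(nrow(sub)), a2)]
    swap <- c2 > c1  # ties keep column order (A,C,G,T), deterministic
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    bases <- colnames(tot)
    maj[idx] <- bases[a1]
    min[idx] <- bases[a2]
    minor_tot <- pmin(c1, c2) + 0
    minor_tot <- ifelse(swap, c1, c2)  # count of allele now in a2
    ok <- minor_tot >= cfg$min_alt_observations_popgen
    status[idx[!ok]] <- "min_alt"
    status[idx[ok]] <- "snp"
  }
  snp_i <- which(status == "snp")
  snps <- data.frame(
    scaffold = sync$sites$scaffold[snp_i], pos = sync$sites$pos[snp_i],
    ref = sync$sites$ref[snp_i],
    major = maj[snp_i], minor = min[snp_i], stringsAsFactors = FALSE)
  if (length(snp_i)) {
    ri <- cbind(snp_i, match(snps$major, colnames(tot)))
    mi <- cbind(snp_i, match(snps$minor, colnames(tot)))
    snps$maj1 <- b1[ri]; snps$min1 <- b1[mi]
    snps$maj2 <- b2[ri]; snps$min2 <- b2[mi]
    snps$p1 <- snps$min1 / (snps$maj1 + snps$min1)
    snps$p2 <- snps$min2 / (snps$maj2 + snps$min2)
    snps$fst <- snp_fst_vec(snps$maj1, snps$min1, snps$maj2, snps$min2)
  } else {
    for (col in c("maj1", "min1", "maj2", "min2", "p1", "p2", "fst"))
      snps[[col]] <- numeric(0)
  }
  list(status = factor(status,
                       levels = c("snp", "monomorphic", "low_coverage",
                                  "min_alt", "triallelic")),
       snps = snps, covered = !low)
}

#' Windowed diversity and differentiation
#'
#' Cuts each scaffold into non-overlapping windows of `window_size` bp
#' (trailing partial windows are discarded) and reports, per window and pool,
#' nucleotide diversity pi (sum of per-site heterozygosity over covered sites
#' divided by the number of covered sites — monomorphic covered sites
#' contribute zero) and window F_ST (unweighted mean of per-SNP F_ST; windows
#' with no SNPs get 0). Windows with fewer than
#' `min_window_covered_fraction` of their sites covered have all statistics
#' set to `NA` and are excluded from tail flagging.
#'
#' @param sync a two-pool `"sync"` object.
#' @param scaffold_lengths named vector of scaffold lengths in bp.
#' @param cfg an [analysis_config()].
#' @param classified optional result of [classify_sites()] to avoid
#'   recomputation.
#' @return A data.frame with scaffold, start, end, n_covered,
#'   covered_fraction, pi_pop1, pi_pop2, n_snps and fst.
#' @export
window_stats <- function(sync, scaffold_lengths, cfg = analysis_config(),
                         classified = NULL) {
  stopifnot(inherits(sync, "sync"), sync$n_pools == 2L)
  if (is.null(classified)) classified <- classify_sites(sync, cfg)
  w <- cfg$window_size
  grids <- lapply(names(scaffold_lengths), function(sc) {
    n_win <- floor(scaffold_lengths[[sc]] / w)
    if (n_win == 0L) return(NULL)
    data.frame(scaffold = sc, start = (seq_len(n_win) - 1L) * w + 1L,
               end = seq_len(n_win) * w, stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, grids)
  if (is.null(win)) stop("no scaffold is at least one window long")
  key <- function(sc, pos) paste0(sc, ":", (pos - 1L) %/% w)
  wkey <- key(win$scaffold, win$start)
  cov_i <- which(classified$covered)
  site_key <- key(sync$sites$scaffold[cov_i], sync$sites$pos[cov_i])
  win$n_covered <- as.integer(table(factor(site_key, levels = wkey)))
  win$covered_fraction <- win$n_covered / w
  # per-site heterozygosity for covered sites, per pool
  b1 <- sync$counts[[1]][cov_i, c("A", "C", "G", "T"), drop = FALSE]
  b2 <- sync$counts[[2]][cov_i, c("A", "C", "G", "T"), drop = FALSE]
  het_of <- function(b) {
    ct <- rowSums(b)
    (ct / (ct - 1)) * (1 - rowSums((b / ct)^2))
  }
  f <- factor(site_key, levels = wkey)
  sum_by <- function(x) {
    s <- tapply(x, f, sum)
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  win$pi_pop1 <- sum_by(het_of(b1)) / win$n_covered
  win$pi_pop2 <- sum_by(het_of(b2)) / win$n_covered
  snps <- classified$snps
  snps <- snps[!is.na(snps$fst), ]
  sf <- factor(key(snps$scaffold, snps$pos), levels = wkey)
  win$n_snps <- as.integer(table(sf))
  fst_sum <- if (nrow(snps)) tapply(snps$fst, sf, sum) else
    numeric(nrow(win))
  fst_sum[is.na(fst_sum)] <- 0
  win$fst <- ifelse(win$n_snps > 0L, as.numeric(fst_sum) / win$n_snps, 0)
  fail <- win$covered_fraction < cfg$min_window_covered_fraction
  win$pi_pop1[fail] <- NA_real_
  win$pi_pop2[fail] <- NA_real_
  win$fst[fail] <- NA_real_
  rownames(win) <- NULL
  win
}

#' Empirical tail thresholds of the window F_ST distribution
#'
#' For each tail fraction f, the threshold is the floor(f * n)-th largest
#' window F_ST (at least the largest), and every window with F_ST greater
#' than or equal to the threshold is flagged — ties at the threshold are all
#' kept. Windows with undefined F_ST are ignored.
#'
#' @param windows data.frame from [window_stats()] (needs an `fst` column).
#' @param fractions upper-tail fractions, each in (0, 1).
#' @return A list with `thresholds` (named by fraction), `flags` (logical
#'   matrix, one column per fraction, rows matching `windows`), and
#'   `tail_means` (mean F_ST of each flagged set).
#' @export
window_tails <- function(windows, fractions = c(0.01, 0.025, 0.05)) {
  fst <- windows$fst
  ok <- !is.na(fst)
  if (!any(ok)) stop("no windows with defined F_ST")
  vals <- sort(fst[ok], decreasing = TRUE)
  n <- length(vals)
  thr <- vapply(fractions, function(f) vals[max(1L, floor(f * n))],
                numeric(1))
  names(thr) <- paste0("tail_", fractions)
  flags <- vapply(thr, function(t) ok & fst >= t, logical(length(fst)))
  flags <- matrix(flags, ncol = length(thr),
                  dimnames = list(NULL, names(thr)))
  means <- vapply(seq_along(thr), function(j)
    mean(fst[flags[, j]]), numeric(1))
  names(means) <- names(thr)
  list(thresholds = thr, flags = flags, tail_means = means)
}
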