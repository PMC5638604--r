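#' Orthologs expressed in both species
#'
#' A one-to-one ortholog is retained when its FPKM exceeds 1 in at least one
#' population sample in each species.
#'
#' @param fpkm_a,fpkm_b data.frames with columns `gene`, `pop1`, `pop2`
#'   (FPKM per population), one per species.
#' @param ortholog_map data.frame with columns `gene_a`, `gene_b` mapping
#'   species A gene ids to species B gene ids (one-to-one).
#' @return The subset of `ortholog_map` whose genes are expressed in both
#'   species, with the four FPKM columns (`a_pop1`, `a_pop2`, `b_pop1`,
#'   `b_pop2`) attached.
#' @export
expressed_orthologs <- function(fpkm_a, fpkm_b, ortholog_map) {
  ia <- match(ortholog_map$gene_a, fpkm_a$gene)
  ib <- match(ortholog_map$gene_b, fpkm_b$gene)
  ok <- !is.na(ia) & !is.na(ib)
  m <- ortholog_map[ok, , drop = FALSE]
  ia <- ia[ok]; ib <- ib[ok]
  m$a_pop1 <- fpkm_a$pop1[ia]; m$a_pop2 <- fpkm_a$pop2[ia]
  m$b_pop1 <- fpkm_b$pop1[ib]; m$b_pop2 <- fpkm_b$pop2[ib]
  keep <- (m$a_pop1 > 1 | m$a_pop2 > 1) & (m$b_pop1 > 1 | m$b_pop2 > 1)
  res <- m[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Log2 fold change between populations with a pseudo-count
#'
#' @param fpkm1,fpkm2 FPKM in population 1 / population 2.
#' @param eps pseudo-count added to both (default 0.1) so zero FPKM is
#'   defined.
#' @return log2((fpkm1 + eps) / (fpkm2 + eps)).
#' @export
log2_fold_change <- function(fpkm1, fpkm2, eps = 0.1) {
  log2((fpkm1 + eps) / (fpkm2 + eps))
}

#' Overlap of the top-N most differentially expressed genes
#'
#' Ranks genes within each species by absolute log2 fold change between the
#' two populations (rank 1 = largest; ties broken by gene id), takes the top
#' N per species, and tests the overlap of the two top lists against the
#' hypergeometric null over the expressed-ortholog universe.
#'
#' @param lfc_a,lfc_b named numeric vectors of log2 fold changes over the
#'   same ortholog ids (names are the shared ids).
#' @param N list size per species.
#' @return An `"overlap_result"` (see [overlap_test()]) with the two top-N
#'   id sets attached as `top_a` and `top_b`.
#' @export
topn_overlap <- function(lfc_a, lfc_b, N) {
  ids <- names(lfc_a)
  stopifnot(!is.null(ids), identical(ids, names(lfc_b)))
  if (N > length(ids)) stop("N exceeds the universe size")
  top_of <- function(lfc) ids[order(-abs(lfc), ids)][seq_len(N)]
  top_a <- top_of(lfc_a)
  top_b <- top_of(lfc_b)
  res <- overlap_test(length(ids), N, N, length(intersect(top_a, top_b)))
  res$top_a <- top_a
  res$top_b <- top_b
  res
}

#' Fold-change magnitude correlation split by direction concordance
#'
#' Splits expressed orthologs into genes whose log2 fold changes agree in
#' sign between the species ("same direction") and genes whose signs differ,
#' excluding genes with a zero fold change in either species, and computes
#' the Pearson correlation of the fold-change magnitudes (|lfc_a| vs
#' |lfc_b|) within each group. Absolute correlation values are reported.
#'
#' @param lfc_a,lfc_b aligned log2 fold-change vectors.
#' @return A list with `r_same`, `r_opp` (absolute Pearson r; `NA` for a
#'   group of fewer than 3 genes), `n_same`, `n_opp` and the logical group
#'   membership vectors `same`, `opp` (aligned with the inputs).
#' @export
direction_split_correlation <- function(lfc_a, lfc_b) {
  nonzero <- lfc_a != 0 & lfc_b != 0
  same <- nonzero & sign(lfc_a) == sign(lfc_b)
  opp <- nonzero & sign(lfc_a) != sign(lfc_b)
  r_of <- function(g) {
    if (sum(g) < 3L) return(NA_real_)
    abs(stats::cor(abs(lfc_a[g]), abs(lfc_b[g])))
  }
  list(r_same = r_of(same), r_opp = r_of(opp),
       n_same = sum(same), n_opp = sum(opp), same = same, opp = opp)
}

#' Compare two correlations by Fisher's z transformation
#'
#' Two-tailed normal test of z1 - z2 with z_i = atanh(r_i) and standard
#' error sqrt(1/(n1 - 3) + 1/(n2 - 3)).
#'
#' @param r1,r2 correlation coefficients with |r| < 1.
#' @param n1,n2 group sizes (>= 4).
#' @return A list with `statistic` and `p`.
#' @examples
#' fisher_z_compare(0.60, 500, 0.56, 500)
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must have absolute value < 1")
  if (n1 < 4 || n2 < 4) stop("group sizes must be at least 4")
  stat <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(statistic = stat, p = 2 * stats::pnorm(-abs(stat)))
}

#' Permutation comparison of the direction-split correlations
#'
#' Size-matched resampling null for the difference between the same- and
#' opposite-direction magnitude correlations: each permutation draws two
#' disjoint random gene sets of the observed group sizes from the pooled
#' (sign-defined) genes, recomputes the two absolute correlations, and the
#' empirical p-value is (1 + #\{|dr_perm| >= |dr_obs|\}) / (reps + 1).
#'
#' @param lfc_a,lfc_b aligned log2 fold-change vectors.
#' @param reps number of permutations (a warning is issued below 100).
#' @param seed integer RNG seed.
#' @return A list with `dr_obs` (r_same - r_opp), `p`, `reps` and `seed`.
#' @export
permutation_compare <- function(lfc_a, lfc_b, reps = 1000L, seed = 1L) {
  if (reps < 100L) warning("fewer than 100 permutations; p is coarse")
  obs <- direction_split_correlation(lfc_a, lfc_b)
  pool <- which(obs$same | obs$opp)
  dr_obs <- obs$r_same - obs$r_opp
  n1 <- obs$n_same; n2 <- obs$n_opp
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  r_of_idx <- function(idx) {
    if (length(idx) < 3L) return(NA_real_)
    abs(stats::cor(abs(lfc_a[idx]), abs(lfc_b[idx])))
  }
  dr_perm <- vapply(seq_len(reps), function(i) {
    sel <- sample(pool, n1 + n2)
    r_of_idx(sel[seq_len(n1)]) - r_of_idx(sel[n1 + seq_len(n2)])
  }, numeric(1))
  list(dr_obs = dr_obs,
       p = (1 + sum(abs(dr_perm) >= abs(dr_obs), na.rm = TRUE)) / (reps + 1),
       reps = reps, seed = seed)
}
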