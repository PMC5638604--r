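#' Build a McDonald-Kreitman count table from a codon alignment
#'
#' Takes three aligned, in-frame, equal-length CDS sequences — the two focal
#' alleles (alternative references carrying the two SNP states) and one
#' outgroup — and counts per-site changes codon by codon. A site where the
#' focal alleles differ is a polymorphism; a site where they agree but differ
#' from the outgroup is a fixed difference. Each change is classified
#' synonymous/nonsynonymous against the focal reference codon (allele 1) with
#' the other two codon positions at their focal-reference state; codons with
#' several variable sites are decomposed site by site in that same context.
#' Codons containing a gap or N in any sequence are skipped. A codon may
#' contribute both a polymorphism and a fixed difference; the two are counted
#' independently.
#'
#' @param focal1,focal2 the two focal allele CDS sequences (character).
#' @param outgroup the aligned outgroup CDS (character).
#' @return A list with counts `Dn`, `Ds`, `Pn`, `Ps` and `n_codons_used`.
#' @examples
#' build_mk_table("ATG", "ATG", "ATA")  # one nonsynonymous fixed difference
#' @export
build_mk_table <- function(focal1, focal2, outgroup) {
  f1 <- toupper(focal1); f2 <- toupper(focal2); og <- toupper(outgroup)
  L <- nchar(f1)
  if (nchar(f2) != L || nchar(og) != L)
    stop("aligned sequences must have equal length")
  if (L %% 3L != 0L) stop("alignment length must be a multiple of 3")
  s1 <- strsplit(f1, "")[[1]]
  s2 <- strsplit(f2, "")[[1]]
  so <- strsplit(og, "")[[1]]
  Dn <- Ds <- Pn <- Ps <- 0L
  used <- 0L
  for (ci in seq_len(L / 3L)) {
    idx <- (ci * 3L - 2L):(ci * 3L)
    c1 <- s1[idx]; c2 <- s2[idx]; co <- so[idx]
    if (any(!c(c1, c2, co) %in% c("A", "C", "G", "T"))) next
    used <- used + 1L
    ref <- paste(c1, collapse = "")
    aa_ref <- translate_codon(ref)
    for (k in 1:3) {
      if (c1[k] != c2[k]) {  # polymorphic site
        mut <- c1; mut[k] <- c2[k]
        if (translate_codon(paste(mut, collapse = "")) == aa_ref)
          Ps <- Ps + 1L else Pn <- Pn + 1L
      }
      if (c1[k] == c2[k] && c1[k] != co[k]) {  # fixed difference
        mut <- c1; mut[k] <- co[k]
        if (translate_codon(paste(mut, collapse = "")) == aa_ref)
          Ds <- Ds + 1L else Dn <- Dn + 1L
      }
    }
  }
  list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps, n_codons_used = used)
}

#' SNP filter for the McDonald-Kreitman pipeline
#'
#' Stricter than the differentiation-scan filter: a site enters the MK
#' tables only when biallelic, with total base-call coverage of at least
#' `min_site_coverage` and the minor allele called at least
#' `min_minor_allele_mk` times (default 3).
#'
#' @param counts combined allele read counts named `A,C,G,T` (or a length-4
#'   vector in that order).
#' @param cfg an [analysis_config()].
#' @return `TRUE` if the site passes, else `FALSE`.
#' @export
mk_filter_snps <- function(counts, cfg = analysis_config()) {
  counts <- as.numeric(counts)
  if (sum(counts) < cfg$min_site_coverage) return(FALSE)
  nz <- counts[counts > 0]
  if (length(nz) != 2L) return(FALSE)
  min(nz) >= cfg$min_minor_allele_mk
}

#' Testability filter for MK tables
#'
#' A gene is testable when it has at least one variant in each of the four
#' marginal categories: polymorphic (Pn + Ps), fixed (Dn + Ds), synonymous
#' (Ps + Ds) and nonsynonymous (Pn + Dn).
#'
#' @param Dn,Ds,Pn,Ps non-negative counts.
#' @return Logical (vectorised).
#' @export
mk_testable <- function(Dn, Ds, Pn, Ps) {
  (Pn + Ps >= 1) & (Dn + Ds >= 1) & (Ps + Ds >= 1) & (Pn + Dn >= 1)
}

#' Unpolarized McDonald-Kreitman test
#'
#' Two-sided Fisher's exact test (minimal-likelihood definition, as in
#' [stats::fisher.test()]) on the 2x2 table \[\[Dn, Ds\], \[Pn, Ps\]\],
#' together with the proportion of adaptive amino-acid fixations
#' alpha = 1 - (Ds Pn) / (Dn Ps) and the direction of selection index
#' DoS = Dn/(Dn + Ds) - Pn/(Pn + Ps). alpha is undefined (`NA`) when Dn = 0
#' or Ps = 0; DoS when either row sum is zero. Neither is clipped.
#'
#' @param Dn,Ds nonsynonymous/synonymous fixed differences.
#' @param Pn,Ps nonsynonymous/synonymous polymorphisms.
#' @return A list with `fisher_p`, `alpha` and `dos`.
#' @examples
#' mk_test(10, 5, 2, 8)
#' @export
mk_test <- function(Dn, Ds, Pn, Ps) {
  tab <- matrix(c(Dn, Ds, Pn, Ps), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  alpha <- if (Dn > 0 && Ps > 0) 1 - (Ds * Pn) / (Dn * Ps) else NA_real_
  dos <- if ((Dn + Ds) > 0 && (Pn + Ps) > 0)
    Dn / (Dn + Ds) - Pn / (Pn + Ps) else NA_real_
  list(fisher_p = p, alpha = alpha, dos = dos)
}

#' Call recurrent adaptive protein evolution
#'
#' A gene shows evidence of recurrent adaptive protein divergence when its MK
#' test rejects neutrality (Fisher p < 0.05) in the adaptive direction:
#' DoS > 0 and alpha > 0. Undefined alpha or DoS never qualifies.
#'
#' @param fisher_p,alpha,dos aligned vectors from [mk_test()].
#' @param p_threshold significance cutoff (default 0.05).
#' @return Logical vector.
#' @export
call_adaptive <- function(fisher_p, alpha, dos, p_threshold = 0.05) {
  out <- fisher_p < p_threshold & dos > 0 & alpha > 0
  out[is.na(out)] <- FALSE
  out
}

#' Classify sex-biased expression
#'
#' A gene is expressed when FPKM > 1 in at least one sex. Among expressed
#' genes, at least two-fold greater FPKM in one sex makes it biased toward
#' that sex, and additionally FPKM <= 0.2 in the other sex makes it
#' sex-specific. Everything else is unbiased.
#'
#' @param fpkm_male,fpkm_female non-negative FPKM vectors.
#' @return Character vector over \{`male_specific`, `male_biased`,
#'   `female_specific`, `female_biased`, `unbiased`, `not_expressed`\}.
#' @export
classify_sex_bias <- function(fpkm_male, fpkm_female) {
  stopifnot(all(fpkm_male >= 0), all(fpkm_female >= 0))
  n <- length(fpkm_male)
  out <- rep("unbiased", n)
  expressed <- fpkm_male > 1 | fpkm_female > 1
  mb <- expressed & fpkm_male >= 2 * fpkm_female
  fb <- expressed & fpkm_female >= 2 * fpkm_male
  out[mb] <- "male_biased"
  out[mb & fpkm_female <= 0.2] <- "male_specific"
  out[fb] <- "female_biased"
  out[fb & fpkm_male <= 0.2] <- "female_specific"
  out[!expressed] <- "not_expressed"
  out
}

#' Chi-square enrichment of a gene class among adaptive genes
#'
#' Pearson chi-square (1 df, no continuity correction) on a 2x2 contingency
#' of class membership by adaptive status.
#'
#' @param tab 2x2 integer matrix with positive margins.
#' @return A list with `chi2` and `p`.
#' @examples
#' enrichment_chi2(matrix(c(30, 70, 10, 90), 2, byrow = TRUE))
#' @export
enrichment_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p = res$p.value)
}

#' Spearman correlation of alpha across clades
#'
#' Rank correlation (average ranks for ties, p-value from the t
#' approximation) of the per-gene alpha estimates of genes showing adaptive
#' protein evolution in both clades.
#'
#' @param alpha_a,alpha_b aligned alpha vectors; pairs with an `NA` are
#'   dropped.
#' @return A list with `rho`, `p` and `n`.
#' @export
alpha_correlation <- function(alpha_a, alpha_b) {
  ok <- stats::complete.cases(alpha_a, alpha_b)
  if (sum(ok) < 3L) stop("need at least 3 complete alpha pairs")
  ct <- suppressWarnings(
    stats::cor.test(alpha_a[ok], alpha_b[ok], method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
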