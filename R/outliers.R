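#' Mid-p exact test of allele-frequency independence
#'
#' Two-sided mid-p odds-ratio test for a 2x2 table of read counts
#' (alleles x populations). With margins fixed, the top-left cell X follows a
#' hypergeometric distribution; the one-sided mid-p values are
#' P(X > a) + 0.5 P(X = a) and P(X < a) + 0.5 P(X = a), and the two-sided
#' mid-p doubles the smaller one (capped at 1) — the central method used by
#' epidemiology toolkits. Counting only half the observed table's probability
#' makes the test less conservative than the standard Fisher exact test.
#'
#' @param a,b,c,d cell counts: `a`,`b` = allele 1/allele 2 reads in
#'   population 1; `c`,`d` = the same in population 2.
#' @return A list with `p` (two-sided mid-p), `p_upper`, `p_lower`,
#'   `odds_ratio` (sample ad/bc), and `degenerate` (`TRUE` when a zero margin
#'   forces p = 1).
#' @examples
#' midp_test(18, 2, 20, 0)
#' @export
midp_test <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; c1 <- a + c; c2 <- b + d; r2 <- c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p = 1, p_upper = 1, p_lower = 1,
                odds_ratio = NA_real_, degenerate = TRUE))
  p_eq <- stats::dhyper(a, c1, c2, r1)
  p_upper <- stats::phyper(a, c1, c2, r1, lower.tail = FALSE) + 0.5 * p_eq
  p_lower <- stats::phyper(a - 1, c1, c2, r1, lower.tail = TRUE) + 0.5 * p_eq
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p = min(1, 2 * min(p_upper, p_lower)),
       p_upper = p_upper, p_lower = p_lower,
       odds_ratio = or, degenerate = FALSE)
}

# vectorised two-sided mid-p over many tables
midp_test_vec <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; r2 <- c + d
  p_eq <- stats::dhyper(a, c1, c2, r1)
  up <- stats::phyper(a, c1, c2, r1, lower.tail = FALSE) + 0.5 * p_eq
  lo <- stats::phyper(a - 1, c1, c2, r1, lower.tail = TRUE) + 0.5 * p_eq
  p <- pmin(1, 2 * pmin(up, lo))
  p[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- 1
  p
}

# Storey pi0 estimate: pi0(lambda) = #{p > lambda} / (m (1 - lambda)) on the
# grid 0.05..0.95, smoothed with a cubic spline (df = 3) and read off at the
# largest lambda, clipped to (0, 1].
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0) return(NA_real_)
  min(pi0, 1)
}

#' Per-chromosome-arm q-values
#'
#' Storey q-values computed independently within each chromosome arm:
#' q_i = pi0 * min over p_j >= p_i of m p_j / rank(p_j), with pi0 estimated by
#' the smoother in `storey_pi0`. Arms with fewer than `min_tests` p-values,
#' or where the smoother fails, fall back to pi0 = 1, i.e. plain
#' Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param arm factor/character of the same length assigning each test to an
#'   arm; a single arm is assumed when `NULL`.
#' @param min_tests minimum number of tests for the pi0 smoother.
#' @return A list with `q` (aligned with `p`) and `arms`, a data.frame of
#'   per-arm `n_tests` and `pi0`.
#' @export
qvalues_per_arm <- function(p, arm = NULL, min_tests = 100L) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(arm)) arm <- rep("all", length(p))
  arm <- as.character(arm)
  q <- rep(NA_real_, length(p))
  arms <- unique(arm)
  pi0s <- numeric(length(arms))
  for (i in seq_along(arms)) {
    idx <- which(arm == arms[i])
    pa <- p[idx]
    pi0 <- if (length(pa) < min_tests) 1 else storey_pi0(pa)
    if (is.na(pi0)) pi0 <- 1
    q[idx] <- pmin(1, pi0 * stats::p.adjust(pa, method = "BH"))
    pi0s[i] <- pi0
  }
  list(q = q,
       arms = data.frame(arm = arms,
                         n_tests = as.integer(table(arm)[arms]),
                         pi0 = pi0s, stringsAsFactors = FALSE))
}

#' Flag F_ST outlier SNPs
#'
#' A SNP is an outlier when its q-value is at most `outlier_fdr` AND its
#' per-SNP F_ST strictly exceeds `outlier_fst` (defaults: q <= 1e-5 and
#' F_ST > 0.15).
#'
#' @param q,fst aligned numeric vectors.
#' @param cfg an [analysis_config()].
#' @return Logical vector; `NA` inputs are never outliers.
#' @export
flag_outliers <- function(q, fst, cfg = analysis_config()) {
  out <- q <= cfg$outlier_fdr & fst > cfg$outlier_fst
  out[is.na(out)] <- FALSE
  out
}

#' Polarize SNPs by an outgroup base
#'
#' A biallelic SNP is polarized only when exactly one of its two alleles
#' equals the aligned outgroup base: that allele is called ancestral, the
#' other derived. SNPs whose outgroup base matches neither allele, or is an
#' N/gap, are excluded (`NA`).
#'
#' @param allele1,allele2 character vectors of the two alleles.
#' @param outgroup character vector of outgroup bases (N or "-" = missing).
#' @return A list of character vectors `ancestral` and `derived` (`NA` when
#'   the SNP cannot be polarized).
#' @export
polarize_ancestral <- function(allele1, allele2, outgroup) {
  outgroup <- toupper(outgroup)
  valid <- outgroup %in% c("A", "C", "G", "T")
  anc <- ifelse(valid & outgroup == allele1, allele1,
                ifelse(valid & outgroup == allele2, allele2, NA_character_))
  der <- ifelse(is.na(anc), NA_character_,
                ifelse(anc == allele1, allele2, allele1))
  list(ancestral = anc, derived = der)
}
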