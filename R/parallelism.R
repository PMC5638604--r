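#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric test of whether two gene sets drawn from a
#' common universe share more members than expected under independence:
#' p = P(X >= k) with X ~ Hypergeometric(N, K, n). The expected overlap is
#' K n / N and the fold enrichment k divided by that expectation.
#'
#' @param N universe size.
#' @param K size of set A.
#' @param n size of set B.
#' @param k observed overlap.
#' @return A list of class `"overlap_result"` with `N`, `K`, `n`, `k`,
#'   `expected`, `fold` and `p`.
#' @examples
#' overlap_test(9401, 640, 1031, 110)
#' @export
overlap_test <- function(N, K, n, k) {
  stopifnot(N >= 1, K >= 0, n >= 0, K <= N, n <= N)
  if (k < max(0, K + n - N) || k > min(K, n))
    stop(sprintf("infeasible overlap k = %d for (N=%d, K=%d, n=%d)",
                 k, N, K, n))
  expected <- K * n / N
  structure(list(N = N, K = K, n = n, k = k,
                 expected = expected,
                 fold = if (expected > 0) k / expected else NaN,
                 p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of (K=%d, n=%d) in universe %d; expected %.2f, %.2f-fold, p = %.3g\n",
    x$k, x$K, x$n, x$N, x$expected, x$fold, x$p))
  invisible(x)
}

# One SNP-count-matched draw: for each required count m (the nsSNP count of
# an outlier gene), pick uniformly at random a not-yet-drawn universe gene
# whose count is >= m. Processing runs from the largest m down so the most
# constrained requirements face the smallest eligible pools first. `ord` is
# the universe ordered by decreasing count; `n_elig` gives, for each required
# m (sorted decreasingly), how many genes qualify.
matched_draw <- function(req_sorted, ord, counts_sorted) {
  pool <- integer(0)     # indices into ord, currently available
  filled <- 0L           # how many of ord have been poured into pool
  drawn <- integer(length(req_sorted))
  i <- 1L
  while (i <= length(req_sorted)) {
    m <- req_sorted[i]
    j <- i
    while (j < length(req_sorted) && req_sorted[j + 1L] == m) j <- j + 1L
    need <- j - i + 1L
    n_elig <- findInterval(-m, -counts_sorted)  # counts_sorted decreasing
    if (n_elig > filled) {
      pool <- c(pool, ord[(filled + 1L):n_elig])
      filled <- n_elig
    }
    if (length(pool) < need)
      stop(sprintf(
        "matched bootstrap: only %d genes with nsSNP count >= %d available for %d draws",
        length(pool), m, need))
    pick <- sample.int(length(pool), need)
    drawn[i:j] <- pool[pick]
    pool <- pool[-pick]
    i <- j + 1L
  }
  drawn
}

#' SNP-count-matched bootstrap null for outlier-gene sharing
#'
#' Tests whether two species' outlier gene sets share more one-to-one
#' orthologs than expected once per-gene nonsynonymous SNP counts are
#' accounted for (larger or SNP-denser genes are more likely to harbor
#' outliers in both species by chance alone). Each replicate replaces every
#' outlier gene with a random universe gene having an equal or greater nsSNP
#' count in that species (drawn without replacement within the replicate),
#' and records the number of shared genes; the empirical p-value uses the
#' add-one form (1 + #\{replicates >= observed\}) / (B + 1).
#'
#' @param universe data.frame over the one-to-one ortholog universe with
#'   columns `gene`, `count_a`, `count_b` (per-species nsSNP counts),
#'   `outlier_a`, `outlier_b` (logical).
#' @param B number of bootstrap replicates.
#' @param seed integer RNG seed (recorded in the result).
#' @return A list of class `"bootstrap_result"` with `k_obs`, `replicates`,
#'   `expected` (mean replicate overlap), `fold`, `p`, `B` and `seed`.
#' @export
matched_bootstrap <- function(universe, B = 1000L, seed = 1L) {
  stopifnot(all(c("gene", "count_a", "count_b", "outlier_a", "outlier_b")
                %in% names(universe)))
  k_obs <- sum(universe$outlier_a & universe$outlier_b)
  prep <- function(counts, outlier) {
    ord <- order(counts, decreasing = TRUE)
    list(req = sort(counts[outlier], decreasing = TRUE),
         ord = ord, counts_sorted = counts[ord])
  }
  a <- prep(universe$count_a, universe$outlier_a)
  b <- prep(universe$count_b, universe$outlier_b)
  reps <- integer(B)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  for (r in seq_len(B)) {
    da <- matched_draw(a$req, a$ord, a$counts_sorted)
    db <- matched_draw(b$req, b$ord, b$counts_sorted)
    reps[r] <- length(intersect(da, db))
  }
  expected <- mean(reps)
  structure(list(k_obs = k_obs, replicates = reps, expected = expected,
                 fold = if (expected > 0) k_obs / expected else NaN,
                 p = (1 + sum(reps >= k_obs)) / (B + 1),
                 B = B, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "matched bootstrap (B = %d): observed %d, expected %.2f, %.2f-fold, p = %.3g\n",
    x$B, x$k_obs, x$expected, x$fold, x$p))
  invisible(x)
}

#' Chi-square test of directional bias
#'
#' Tests counts of SNPs whose derived allele is at higher frequency in
#' population 1 (`n_up`) versus population 2 (`n_down`) against a 50:50
#' expectation, Pearson chi-square with 1 df and no continuity correction.
#'
#' @param n_up,n_down non-negative counts, not both zero.
#' @return A list with `n_up`, `n_down`, `chi2` and `p`.
#' @examples
#' direction_chi2(606, 394)
#' @export
direction_chi2 <- function(n_up, n_down) {
  tot <- n_up + n_down
  if (tot <= 0) stop("n_up + n_down must be positive")
  e <- tot / 2
  chi2 <- (n_up - e)^2 / e + (n_down - e)^2 / e
  list(n_up = n_up, n_down = n_down, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Fisher's combined probability
#'
#' Combines independent p-values via X = -2 sum log p_i, referred to a
#' chi-square distribution with 2k degrees of freedom.
#'
#' @param p vector of p-values in (0, 1].
#' @return The combined p-value.
#' @examples
#' fishers_combined(c(0.05, 0.22))  # ~0.06
#' @export
fishers_combined <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# Seed handling: run a block under a caller-supplied seed without disturbing
# the session RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
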