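#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline into a validated list.
#' The defaults are the study's operating point: pooled sites enter the
#' population-genetic analysis at a minimum of 20x coverage in each pool with
#' at least two observations of the alternate base across the whole dataset;
#' SNPs entering the McDonald-Kreitman analysis additionally require the minor
#' allele called at least 3 times; windows are 1 kb, non-overlapping, and must
#' have at least 50% of their sites covered; F_ST outliers require q <= 1e-5
#' and per-SNP F_ST > 0.15; the sharing bootstrap uses 1000 replicates; the
#' expression comparison ranks the top 300 genes.
#'
#' @param min_site_coverage minimum per-pool read depth (base calls only) for
#'   a site to be considered covered.
#' @param min_alt_observations_popgen minimum count of the alternate allele,
#'   summed over pools, for a biallelic site to be kept as a SNP.
#' @param min_minor_allele_mk minimum minor-allele count for SNPs feeding the
#'   McDonald-Kreitman tables (stricter than the scan filter).
#' @param window_size window length in bp for windowed diversity and F_ST.
#' @param min_window_covered_fraction minimum fraction of covered sites for a
#'   window to be reported.
#' @param outlier_fdr q-value cutoff for calling a SNP an outlier.
#' @param outlier_fst per-SNP F_ST that an outlier must strictly exceed.
#' @param window_tail_fractions upper-tail fractions of the window F_ST
#'   distribution to flag.
#' @param bootstrap_reps replicates for the SNP-count-matched sharing null.
#' @param top_n_expression genes per species in the expression overlap.
#' @param top_n_snps genes per species in the rank-based SNP-outlier overlap.
#' @param flank_bp gene-region flank (upstream/downstream of the transcript).
#' @param rng_seed integer seed recorded in run manifests.
#' @return A list of class `"paradapt_config"`.
#' @examples
#' cfg <- analysis_config()
#' cfg$min_site_coverage
#' @export
analysis_config <- function(min_site_coverage = 20,
                            min_alt_observations_popgen = 2,
                            min_minor_allele_mk = 3,
                            window_size = 1000,
                            min_window_covered_fraction = 0.5,
                            outlier_fdr = 1e-5,
                            outlier_fst = 0.15,
                            window_tail_fractions = c(0.01, 0.025, 0.05),
                            bootstrap_reps = 1000,
                            top_n_expression = 300,
                            top_n_snps = 400,
                            flank_bp = 1000,
                            rng_seed = 1L) {
  cfg <- list(
    min_site_coverage = min_site_coverage,
    min_alt_observations_popgen = min_alt_observations_popgen,
    min_minor_allele_mk = min_minor_allele_mk,
    window_size = window_size,
    min_window_covered_fraction = min_window_covered_fraction,
    outlier_fdr = outlier_fdr,
    outlier_fst = outlier_fst,
    window_tail_fractions = window_tail_fractions,
    bootstrap_reps = bootstrap_reps,
    top_n_expression = top_n_expression,
    top_n_snps = top_n_snps,
    flank_bp = flank_bp,
    rng_seed = as.integer(rng_seed)
  )
  num <- cfg[setdiff(names(cfg), "rng_seed")]
  if (!all(vapply(num, function(x) is.numeric(x) && all(x > 0), logical(1))))
    stop("all configuration thresholds must be positive numbers")
  if (any(window_tail_fractions <= 0 | window_tail_fractions >= 1))
    stop("window_tail_fractions must lie strictly in (0, 1)")
  if (min_window_covered_fraction > 1)
    stop("min_window_covered_fraction must lie in (0, 1]")
  class(cfg) <- "paradapt_config"
  cfg
}

#' @export
print.paradapt_config <- function(x, ...) {
  cat("paradapt analysis configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
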