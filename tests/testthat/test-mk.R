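test_that("codon alignments yield the expected MK counts", {
  # fixed nonsynonymous difference: both focal alleles ATG, outgroup ATA
  r <- build_mk_table("ATG", "ATG", "ATA")
  expect_equal(r[c("Dn", "Ds", "Pn", "Ps")],
               list(Dn = 1L, Ds = 0L, Pn = 0L, Ps = 0L))
  # synonymous polymorphism: CTG vs CTA, outgroup CTG
  r <- build_mk_table("CTG", "CTA", "CTG")
  expect_equal(r$Ps, 1L); expect_equal(r$Pn + r$Dn + r$Ds, 0L)
  # gap/N codons are skipped
  r <- build_mk_table("ATGNNN", "ATGAAA", "ATAAAA")
  expect_equal(r$n_codons_used, 1L)
  expect_equal(r$Dn, 1L)
  # a codon can contribute a polymorphism and a fixed difference at once
  r <- build_mk_table("CTG", "CTA", "TTG")  # pos3 poly (syn), pos1 fixed
  expect_equal(r$Ps, 1L)
  expect_equal(r$Dn + r$Ds, 1L)
  # frame/length violations
  expect_error(build_mk_table("ATGA", "ATGA", "ATGA"), "multiple of 3")
  expect_error(build_mk_table("ATG", "ATGAAA", "ATG"), "equal length")
  # planted synthetic gene recovers the generator's truth table exactly
  aln <- paradapt:::plant_mk_alignment(2, 1, 1, 3)
  r <- build_mk_table(aln[1], aln[2], aln[3])
  expect_equal(r[c("Dn", "Ds", "Pn", "Ps")],
               list(Dn = 2L, Ds = 1L, Pn = 1L, Ps = 3L))
})

test_that("MK SNP filter enforces coverage 20 and minor allele >= 3", {
  cfg <- analysis_config()
  expect_true(mk_filter_snps(c(A = 22, C = 3, G = 0, T = 0), cfg))
  expect_false(mk_filter_snps(c(A = 23, C = 2, G = 0, T = 0), cfg))
  expect_false(mk_filter_snps(c(A = 16, C = 3, G = 0, T = 0), cfg))
  expect_false(mk_filter_snps(c(A = 20, C = 3, G = 3, T = 0), cfg))
})

test_that("testability needs one variant in all four marginal categories", {
  expect_true(mk_testable(2, 1, 1, 3))
  expect_false(mk_testable(0, 3, 0, 5))   # no nonsynonymous variant
  expect_true(mk_testable(2, 0, 0, 3))    # marginals all positive
  expect_false(mk_testable(0, 0, 1, 1))   # no fixed variant
})

test_that("MK statistics match their closed forms and the Fisher oracle", {
  r <- mk_test(10, 5, 10, 5)
  expect_equal(r$alpha, 0); expect_equal(r$dos, 0)
  expect_equal(r$fisher_p, 1)
  r <- mk_test(10, 5, 2, 8)
  expect_equal(r$alpha, 1 - (5 * 2) / (10 * 8))
  expect_equal(r$dos, 10 / 15 - 2 / 10)
  expect_equal(r$fisher_p, fisher_oracle(10, 5, 2, 8), tolerance = 1e-12)
  # undefined alpha and DoS are explicit
  expect_true(is.na(mk_test(0, 5, 2, 8)$alpha))
  expect_true(is.na(mk_test(10, 5, 2, 0)$alpha))
  expect_true(is.na(mk_test(0, 0, 2, 8)$dos))
  # Fisher p equals enumeration on random tables with total <= 40
  set.seed(14)
  for (i in 1:300) {
    tot <- sample(4:40, 1)
    cells <- rmultinom(1, tot, rep(0.25, 4))[, 1]
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    expect_equal(mk_test(cells[1], cells[2], cells[3], cells[4])$fisher_p,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("adaptive calls require significance in the adaptive direction", {
  expect_true(call_adaptive(0.01, 0.5, 0.2))
  expect_false(call_adaptive(0.01, -0.4, -0.1))
  expect_false(call_adaptive(0.06, 0.9, 0.5))
  expect_false(call_adaptive(0.01, NA, 0.5))
  # monotone non-increasing in the p threshold
  set.seed(15)
  p <- runif(200); al <- runif(200, -1, 1); d <- runif(200, -0.5, 0.5)
  n_weak <- sum(call_adaptive(p, al, d, p_threshold = 0.1))
  n_strict <- sum(call_adaptive(p, al, d, p_threshold = 0.01))
  expect_lte(n_strict, n_weak)
})

test_that("sex-bias classes partition every FPKM pair", {
  expect_equal(classify_sex_bias(5, 2), "male_biased")
  expect_equal(classify_sex_bias(5, 0.1), "male_specific")
  expect_equal(classify_sex_bias(1.5, 1.0), "unbiased")
  expect_equal(classify_sex_bias(0.2, 4), "female_specific")
  expect_equal(classify_sex_bias(2, 4.5), "female_biased")
  expect_equal(classify_sex_bias(0.9, 0.3), "not_expressed")
  # exhaustive grid: exactly one class each, and the specific => biased rule
  grid <- expand.grid(m = c(0, 0.1, 0.2, 0.5, 1, 1.01, 2, 5, 50),
                      f = c(0, 0.1, 0.2, 0.5, 1, 1.01, 2, 5, 50))
  cls <- classify_sex_bias(grid$m, grid$f)
  expect_true(all(cls %in% c("male_specific", "male_biased",
                             "female_specific", "female_biased",
                             "unbiased", "not_expressed")))
  ms <- cls == "male_specific"
  expect_true(all(grid$f[ms] <= 0.2 & grid$m[ms] >= 2 * grid$f[ms]))
  expect_true(all((grid$m > 1 | grid$f > 1) == (cls != "not_expressed")))
})

test_that("enrichment chi-square matches the hand formula and is symmetric", {
  tab <- matrix(c(30, 70, 10, 90), 2, byrow = TRUE)
  r <- enrichment_chi2(tab)
  expect_equal(r$chi2, 12.5)
  expect_equal(r$p, 4.07e-4, tolerance = 1e-2)
  expect_equal(enrichment_chi2(t(tab))$chi2, r$chi2)
  expect_equal(enrichment_chi2(tab[2:1, ])$chi2, r$chi2)
  even <- matrix(c(20, 80, 10, 40), 2, byrow = TRUE)
  expect_equal(enrichment_chi2(even)$chi2, 0)
  expect_equal(enrichment_chi2(even)$p, 1)
  expect_error(enrichment_chi2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("alpha correlation is a tie-aware Spearman rank correlation", {
  expect_equal(alpha_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(alpha_correlation(1:10, -(1:10))$rho, -1)
  expect_error(alpha_correlation(c(1, 2), c(2, 1)), "at least 3")
  # explicit rank oracle with ties: Pearson correlation of average ranks
  set.seed(16)
  x <- c(0.1, 0.5, 0.5, 0.9, 0.2, 0.7, 0.7, 0.7, 0.3, 0.4)
  y <- rnorm(10)
  expect_equal(alpha_correlation(x, y)$rho,
               cor(rank(x), rank(y)), tolerance = 1e-12)
  # NA pairs are dropped
  expect_equal(alpha_correlation(c(x, NA), c(y, 1))$n, 10)
})
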