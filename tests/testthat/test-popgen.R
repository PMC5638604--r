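test_that("site heterozygosity matches the corrected pooled formula", {
  expect_equal(site_heterozygosity(c(10, 10)), (20 / 19) * 0.5)
  expect_equal(site_heterozygosity(c(20, 0)), 0)
  expect_equal(site_heterozygosity(c(15, 5)), (20 / 19) * (1 - 0.625))
  expect_error(site_heterozygosity(c(1, 0)), "at least 2")
  # bounds: 0 <= H <= c/(c-1) * (1 - 1/k); zero iff monomorphic
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    cts <- rmultinom(1, sample(20:80, 1), rep(1 / k, k))[, 1]
    h <- site_heterozygosity(cts)
    ct <- sum(cts)
    expect_gte(h, 0)
    expect_lte(h, ct / (ct - 1) * (1 - 1 / k) + 1e-12)
    expect_identical(h == 0, sum(cts > 0) == 1L)
  }
})

test_that("the corrected estimator is unbiased for 2p(1-p) under read sampling", {
  set.seed(42)
  p <- 0.3; cov <- 60; nrep <- 10000
  a <- rbinom(nrep, cov, p)
  h <- (cov / (cov - 1)) * (1 - (a / cov)^2 - ((cov - a) / cov)^2)
  se <- sd(h) / sqrt(nrep)
  expect_lt(abs(mean(h) - 2 * p * (1 - p)), 3 * se)
})

test_that("site filter applies coverage, biallelic and min-alt rules", {
  cfg <- analysis_config()
  r <- filter_site(list(sx(A = 18, C = 2), sx(A = 20)), cfg)
  expect_equal(r$status, "snp")
  expect_equal(r$major, "A"); expect_equal(r$minor, "C")
  expect_equal(filter_site(list(sx(A = 19, C = 1), sx(A = 20)), cfg)$status,
               "min_alt")
  expect_equal(filter_site(list(sx(A = 10, T = 5, C = 5), sx(A = 20)),
                           cfg)$status, "triallelic")
  expect_equal(filter_site(list(sx(A = 15, T = 4), sx(A = 20)), cfg)$status,
               "low_coverage")
  expect_equal(filter_site(list(sx(A = 25), sx(A = 20)), cfg)$status,
               "monomorphic")
})

test_that("per-SNP F_ST has the right identities and limits", {
  expect_equal(snp_fst(c(20, 0), c(0, 20)), 1)
  expect_equal(snp_fst(c(15, 5), c(5, 15)), 0.23026, tolerance = 1e-4)
  expect_true(is.na(snp_fst(c(20, 0), c(20, 0))))  # monomorphic combined
  # identical pools: a small negative finite-coverage bias of order -1/(2c)
  # that vanishes as counts scale (consequence of the c/(c-1) correction
  # entering pi_total at 2c but pi_within at c)
  set.seed(2)
  for (i in 1:20) {
    x <- c(sample(5:40, 1), sample(5:40, 1))
    f <- snp_fst(x, x)
    expect_lte(f, 0)
    expect_gt(f, -1 / sum(x))
    expect_equal(snp_fst(x * 1000, x * 1000), 0, tolerance = 1e-4)
  }
  # infinite-coverage limit: counts x1000 converge to the frequency version
  p1 <- 0.75; p2 <- 0.25
  freq_fst <- {
    pit <- 2 * 0.5 * 0.5
    piw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    (pit - piw) / pit
  }
  expect_equal(snp_fst(c(15000, 5000), c(5000, 15000)), freq_fst,
               tolerance = 1e-3)
})

test_that("classify_sites agrees with the scalar filter on every site", {
  set.seed(3)
  n <- 200
  pools <- lapply(1:2, function(j) {
    m <- matrix(0L, n, 6)
    m[, 1] <- rpois(n, 30)
    m[, 3] <- rbinom(n, 10, 0.3)
    m[sample(n, 10), 2] <- 5L  # some triallelic
    m[sample(n, 10), 1] <- 2L  # some low coverage
    m
  })
  s <- make_sync(seq_len(n), pools[[1]], pools[[2]])
  cl <- classify_sites(s)
  cfg <- analysis_config()
  for (i in seq_len(n)) {
    scalar <- filter_site(list(pools[[1]][i, ], pools[[2]][i, ]), cfg)
    expect_equal(as.character(cl$status[i]), scalar$status, info = i)
  }
  # SNP F_ST column agrees with the scalar computation
  j <- which(cl$status == "snp")[1]
  sc <- filter_site(list(pools[[1]][j, ], pools[[2]][j, ]), cfg)
  expect_equal(cl$snps$fst[1],
               snp_fst(sc$counts[1, ], sc$counts[2, ]))
})

make_window_sync <- function(n_sites, snp_rows = NULL, cov = 30L) {
  m1 <- m2 <- matrix(0L, n_sites, 6)
  m1[, 1] <- cov; m2[, 1] <- cov
  if (!is.null(snp_rows)) {
    for (r in names(snp_rows)) {
      i <- as.integer(r)
      m1[i, ] <- snp_rows[[r]][[1]]
      m2[i, ] <- snp_rows[[r]][[2]]
    }
  }
  make_sync(seq_len(n_sites), m1, m2)
}

test_that("window pi uses covered sites as denominator and a 50% rule", {
  cfg <- analysis_config()
  # 1000 covered monomorphic sites -> pi = 0, fst = 0 (no SNPs)
  s <- make_window_sync(1000)
  w <- window_stats(s, c(scf1 = 1000), cfg)
  expect_equal(nrow(w), 1L)
  expect_equal(w$pi_pop1, 0); expect_equal(w$fst, 0)
  # one SNP with pool-1 heterozygosity (20/19)(1-0.625)
  s <- make_window_sync(1000, list(`500` = list(sx(A = 15, C = 5),
                                                sx(A = 20))))
  w <- window_stats(s, c(scf1 = 1000), cfg)
  expect_equal(w$pi_pop1, (20 / 19) * (1 - 0.625) / 1000, tolerance = 1e-9)
  expect_equal(w$n_snps, 1L)
  # 499 of 1000 covered -> undefined
  s <- make_window_sync(1000)
  s$counts[[1]][1:501, 1] <- 5L
  w <- window_stats(s, c(scf1 = 1000), analysis_config())
  expect_equal(w$n_covered, 499L)
  expect_true(is.na(w$pi_pop1) && is.na(w$fst))
  # trailing partial window discarded
  s <- make_window_sync(1500)
  w <- window_stats(s, c(scf1 = 1500), cfg)
  expect_equal(nrow(w), 1L)
  expect_equal(w$end, 1000L)
})

test_that("window F_ST is the unweighted SNP mean", {
  snps <- list(`100` = list(sx(A = 15, C = 5), sx(A = 5, C = 15)),
               `200` = list(sx(A = 18, C = 2), sx(A = 20)))
  s <- make_window_sync(1000, snps)
  w <- window_stats(s, c(scf1 = 1000), analysis_config())
  f1 <- snp_fst(c(15, 5), c(5, 15))
  f2 <- snp_fst(c(18, 2), c(20, 0))
  expect_equal(w$fst, mean(c(f1, f2)))
})

test_that("genome mean of fully covered window pi equals the site-level ratio", {
  set.seed(4)
  n <- 3000
  m1 <- m2 <- matrix(0L, n, 6)
  m1[, 1] <- 25L; m2[, 1] <- 25L
  snp_at <- sample(n, 60)
  m1[snp_at, 3] <- rbinom(60, 8, 0.5); m2[snp_at, 3] <- rbinom(60, 8, 0.5)
  m1[snp_at, 1] <- 25L - m1[snp_at, 3]; m2[snp_at, 1] <- 25L - m2[snp_at, 3]
  s <- make_sync(seq_len(n), m1, m2)
  w <- window_stats(s, c(scf1 = n), analysis_config())
  het <- apply(m1[, c(1, 3)], 1, function(x)
    if (sum(x) >= 2) site_heterozygosity(x) else 0)
  expect_equal(mean(w$pi_pop1), sum(het) / n, tolerance = 1e-12)
})

test_that("window tails flag the top fraction with ties kept", {
  w <- data.frame(fst = (1:1000) / 1000)
  t5 <- window_tails(w, 0.05)
  expect_equal(unname(t5$thresholds), 0.951)
  expect_equal(sum(t5$flags), 50L)
  # all equal -> all flagged at every fraction
  weq <- data.frame(fst = rep(0.2, 40))
  teq <- window_tails(weq, c(0.01, 0.05))
  expect_true(all(teq$flags))
  # two windows at f = 0.5 -> only the larger flagged
  t2 <- window_tails(data.frame(fst = c(0.1, 0.4)), 0.5)
  expect_equal(unname(t2$flags[, 1]), c(FALSE, TRUE))
  expect_error(window_tails(data.frame(fst = NA_real_), 0.05), "no windows")
})
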