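test_that("exact HWE test matches the enumeration oracle on random tables", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)   # monomorphic
  expect_equal(hwe_exact_test(0, 0, 25), 1)
  set.seed(70)
  for (i in 1:50) {
    n <- sample(2:150, 1)
    n_Aa <- sample(0:n, 1)
    n_aa <- sample(0:(n - n_Aa), 1)
    n_AA <- n - n_Aa - n_aa
    expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                 oracle_hwe_p(n_AA, n_Aa, n_aa), tolerance = 1e-12)
  }
  # extreme heterozygote excess in 100 individuals
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("QC filtering removes exactly the planted failures, in order", {
  # panel wide enough that planted per-SNP missingness does not push any
  # sample over its own missingness threshold
  panel <- simulate_null_panel(1000, 500, missing_rate = 0,
                               n_low_call = 50, n_hwe_violators = 10,
                               n_low_maf = 15, low_maf = 0.002, seed = 71)
  rep <- qc_filter(panel$genotypes, qc_config())
  expect_true(all(rep$samples$pass))

  got <- rep$snps$reason
  expect_identical(got[panel$label == "low_call"],
                   rep("call_rate", 50))
  expect_identical(got[panel$label == "hwe_violation"], rep("hwe", 10))
  expect_identical(got[panel$label == "low_maf"], rep("maf", 15))
  expect_true(all(is.na(got[panel$label == "clean"])))
  expect_equal(ncol(rep$genotypes), 1000 - 75)
})

test_that("sample missingness is filtered before SNP call rates", {
  set.seed(72)
  G <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20)
  # five samples missing 30% of genotypes
  for (i in 1:5) G[i, sample(20, 6)] <- NA
  rep <- qc_filter(G, qc_config(max_sample_missing = 0.02))
  expect_equal(sum(!rep$samples$pass), 5)
  # once the bad samples are gone, every SNP has full call rate again
  expect_true(all(rep$snps$call_rate == 1))
})

test_that("QC is idempotent and tolerates filtering everything", {
  panel <- simulate_null_panel(100, 1000, missing_rate = 0.01,
                               n_low_call = 10, seed = 73)
  first <- qc_filter(panel$genotypes)
  second <- qc_filter(first$genotypes)
  expect_true(all(second$snps$pass))
  expect_true(all(second$samples$pass))
  expect_identical(dim(second$genotypes), dim(first$genotypes))

  all_bad <- matrix(NA_integer_, 10, 3)
  rep <- qc_filter(all_bad)
  expect_equal(ncol(rep$genotypes), 0)
})

test_that("the genome scan matches per-SNP Levene tests and flags the causal SNP", {
  set.seed(74)
  n <- 1500
  panel <- simulate_null_panel(40, n, seed = 75)
  G <- panel$genotypes
  covar <- rnorm(n)
  g7 <- G[, 7] - mean(G[, 7])
  y <- 0.3 * covar + 0.6 * g7 * covar + rnorm(n)

  scan <- genome_scan_levene(y, G, scan_alpha = 0.05 / 40)
  # redundant-path equality with levene_by_genotype
  for (j in c(1, 7, 22)) {
    expect_equal(scan$snps$levene_p[j], levene_by_genotype(y, G[, j])$p.value)
    expect_equal(scan$snps$W[j],
                 unname(levene_by_genotype(y, G[, j])$statistic))
  }
  expect_equal(which.min(scan$snps$levene_p), 7L)
  expect_true(scan$snps$significant[7])
  expect_equal(scan$snps$n0[7] + scan$snps$n1[7] + scan$snps$n2[7],
               scan$snps$n_used[7])
})

test_that("a null scan is calibrated and its QQ data well-formed", {
  set.seed(76)
  n_snps <- 400
  G <- matrix(rbinom(800 * n_snps, 2, 0.3), 800, n_snps)
  y <- rnorm(800)
  scan <- genome_scan_levene(y, G, scan_alpha = 1e-7)
  p <- scan$snps$levene_p
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_snps))
  expect_lt(abs(mean(p < 0.01) - 0.01), 3 * sqrt(0.01 * 0.99 / n_snps))
  q <- scan$qq
  expect_equal(nrow(q), n_snps)
  expect_true(!is.unsorted(q$observed))
  # roughly 95% of points inside the pointwise 95% band
  inside <- mean(q$observed >= q$band_lo & q$observed <= q$band_hi)
  expect_gt(inside, 0.85)
})

test_that("qq_data handles empty and NA-laden input", {
  expect_equal(nrow(qq_data(c(NA, NA))), 0)
  q <- qq_data(c(0.2, NA, 0.9, 0.01))
  expect_equal(q$observed, c(0.01, 0.2, 0.9))
})

test_that("adjusting for the causal interaction removes the variance signal", {
  set.seed(77)
  m <- trait_model(0.3, beta2 = 0.3, interaction_fraction = 0.01)
  reps <- 200
  p_adj <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- simulate_gxe(m, 2000)
    p_adj[i] <- levene_adjusted(d$y, d$counts1, d$covariate)$p.value
  }
  # adjusted p-values are null-distributed
  expect_lt(abs(mean(p_adj < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(ks.test(p_adj, "punif")$p.value, 0.01)
})

test_that("under no interaction, adjustment barely perturbs the Levene p-value", {
  # with no covariate effect at all, the adjustment regression removes only
  # an O(1/n) fitted component, so raw and adjusted screens nearly coincide;
  # when beta2 != 0 the adjustment also strips the covariate main effect
  # from the deviations and the two p-values differ by design (their joint
  # calibration is checked above)
  set.seed(78)
  m0 <- trait_model(0.3)
  reps <- 150
  p_raw <- p_adj <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- simulate_gxe(m0, 800)
    p_raw[i] <- levene_by_genotype(d$y, d$counts1)$p.value
    p_adj[i] <- levene_adjusted(d$y, d$counts1, d$covariate)$p.value
  }
  expect_gt(cor(p_raw, p_adj, method = "spearman"), 0.95)
})

test_that("adjusting one of two interactions attenuates but keeps the signal", {
  set.seed(79)
  n <- 20000
  counts <- rbinom(n, 2, 0.3)
  g <- counts - 2 * 0.3
  c1 <- rnorm(n); c2 <- rnorm(n)
  y <- 0.3 * c1 + 0.2 * c2 + 0.15 * g * c1 + 0.15 * g * c2 + rnorm(n)
  raw <- levene_by_genotype(y, counts)
  adj <- levene_adjusted(y, counts, c1)
  expect_lt(raw$p.value, adj$p.value)   # attenuated ...
  expect_lt(adj$p.value, 1e-4)          # ... but still clearly non-null
})
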