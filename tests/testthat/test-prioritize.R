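test_that("interaction regression recovers a noiseless coefficient exactly", {
  set.seed(50)
  g <- center_genotype(rbinom(100, 2, 0.3), 0.3)
  c_ <- rnorm(100)
  y <- 1 + 0.2 * g + 0.4 * c_ + 0.5 * g * c_
  fit <- interaction_regression(y, g, c_)
  expect_equal(fit$beta3_hat, 0.5, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-100)
})

test_that("coefficient, SE and p-value match the normal-equations oracle and lm", {
  d <- make_fixed_dataset(20)
  fit <- interaction_regression(d$y, d$g, d$c_)
  oracle <- oracle_ols_interaction(d$y, d$g, d$c_)
  expect_equal(fit$beta3_hat, oracle$beta3, tolerance = 1e-10)
  expect_equal(fit$se, oracle$se, tolerance = 1e-10)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)

  lmfit <- summary(lm(d$y ~ d$g * d$c_))
  expect_equal(fit$beta3_hat, lmfit$coefficients[4, 1], tolerance = 1e-10)
  expect_equal(fit$se, lmfit$coefficients[4, 2], tolerance = 1e-10)
  expect_equal(fit$p_value, lmfit$coefficients[4, 4], tolerance = 1e-10)
  expect_equal(unname(coef(fit)), unname(coef(lm(d$y ~ d$g * d$c_))),
               tolerance = 1e-10)
})

test_that("interaction test has nominal type-I error under the null", {
  set.seed(51)
  reps <- 4000
  p <- vapply(seq_len(reps), function(i) {
    g <- rbinom(150, 2, 0.3) - 0.6
    c_ <- rnorm(150)
    y <- 0.3 * c_ + rnorm(150)
    interaction_regression(y, g, c_)$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("degenerate designs are flagged, with pairwise NA deletion", {
  mono <- interaction_regression(rnorm(50), rep(0.4, 50), rnorm(50))
  expect_true(mono$degenerate)
  const <- interaction_regression(rnorm(50), rbinom(50, 2, 0.4), rep(1, 50))
  expect_true(const$degenerate)
  tiny <- interaction_regression(rnorm(4), rnorm(4), rnorm(4))
  expect_true(tiny$degenerate)

  y <- rnorm(60); y[3] <- NA
  g <- rbinom(60, 2, 0.3); c_ <- rnorm(60); c_[10] <- NA
  fit <- interaction_regression(y, g, c_)
  expect_equal(fit$n_used, 58)
})

test_that("corrected thresholds reproduce the published accounting", {
  # screening at 0.01 over 340,000 SNPs: 0.05 / (0.01 * 340,000)
  expect_equal(corrected_threshold(prioritization_config(0.01)),
               0.05 / (0.01 * 340000))
  # vacuous screen collapses to the exhaustive Bonferroni thresholds
  expect_equal(signif(corrected_threshold(prioritization_config(1)), 2),
               1.5e-07)
  expect_equal(signif(corrected_threshold(
    prioritization_config(1, mode = "gxg")), 2), 4.3e-13)
  # multiple declared covariates enter multiplicatively
  expect_equal(corrected_threshold(
    prioritization_config(1, panel_size = 3, n_covariates = 6)),
    0.05 / 18)
})

test_that("corrected threshold is monotone in M, alpha_L and fwer", {
  # threshold = fwer / (alpha_L * M): decreasing in M and alpha_L (a looser
  # screen admits more tests to correct for), increasing in the error budget
  base <- prioritization_config(0.05, panel_size = 1e5)
  bigger_m <- prioritization_config(0.05, panel_size = 2e5)
  looser_screen <- prioritization_config(0.1, panel_size = 1e5)
  bigger_budget <- prioritization_config(0.05, panel_size = 1e5, fwer = 0.1)
  expect_lt(corrected_threshold(bigger_m), corrected_threshold(base))
  expect_lt(corrected_threshold(looser_screen), corrected_threshold(base))
  expect_gt(corrected_threshold(bigger_budget), corrected_threshold(base))
})

test_that("a planted strong interaction is found with its partner named", {
  set.seed(52)
  n <- 800
  panel <- simulate_null_panel(10, n, seed = 53)
  G <- panel$genotypes
  covars <- cbind(bmi = rnorm(n), smoke = rnorm(n))
  g3 <- G[, 3] - mean(G[, 3])
  y <- 0.3 * covars[, "bmi"] + 1.0 * g3 * covars[, "bmi"] + rnorm(n)
  cfg <- prioritization_config(0.05, panel_size = 10, n_covariates = 2)
  res <- prioritize_and_test(y, G, covars, cfg)
  hits <- res$tests[res$tests$significant, ]
  expect_true(any(hits$snp == "snp3" & hits$partner == "bmi"))
})

test_that("a vacuous screen reproduces the exhaustive significant set", {
  set.seed(54)
  n <- 400
  panel <- simulate_null_panel(8, n, seed = 55)
  G <- panel$genotypes
  covar <- cbind(c1 = rnorm(n))
  g2 <- G[, 2] - mean(G[, 2])
  y <- 0.8 * g2 * covar[, 1] + rnorm(n)

  screened <- prioritize_and_test(y, G, covar,
                                  prioritization_config(1, panel_size = 8))
  # exhaustive search: every SNP tested at the same 0.05/M threshold
  exhaustive <- vapply(seq_len(ncol(G)), function(j) {
    gj <- G[, j] - mean(G[, j])
    interaction_regression(y, gj, covar[, 1])$p_value
  }, numeric(1))
  expect_setequal(screened$tests$snp[screened$tests$significant],
                  colnames(G)[exhaustive < 0.05 / 8])
  expect_equal(screened$n_prioritized, ncol(G))
})

test_that("gene-by-gene pairs with both SNPs prioritized are tested once", {
  set.seed(56)
  n <- 500
  G <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.4),
             c = rbinom(n, 2, 0.2))
  ga <- G[, 1] - mean(G[, 1]); gb <- G[, 2] - mean(G[, 2])
  y <- 1.2 * ga * gb + rnorm(n)
  res <- prioritize_and_test(y, G, config =
                               prioritization_config(1, panel_size = 3,
                                                     mode = "gxg"))
  pair_keys <- apply(res$tests[c("snp", "partner")], 1,
                     function(r) paste(sort(r), collapse = "|"))
  expect_false(any(duplicated(pair_keys)))
  # 3 unordered pairs in a 3-SNP panel with a vacuous screen
  expect_equal(nrow(res$tests), 3)
  expect_true(any(res$tests$significant &
                    pair_keys == "a|b"))
})

test_that("two-step family-wise error under the global null stays below budget", {
  set.seed(57)
  reps <- 150
  n_snps <- 30
  cfg <- prioritization_config(0.05, panel_size = n_snps)
  false_pos <- vapply(seq_len(reps), function(i) {
    G <- matrix(rbinom(200 * n_snps, 2, 0.3), 200, n_snps)
    y <- rnorm(200)
    covar <- cbind(c1 = rnorm(200))
    res <- prioritize_and_test(y, G, covar, cfg)
    any(res$tests$significant)
  }, logical(1))
  fwer_hat <- mean(false_pos)
  expect_lte(fwer_hat, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("empty prioritized sets return empty results, and tables serialize", {
  set.seed(58)
  G <- matrix(rbinom(100 * 5, 2, 0.3), 100, 5)
  y <- rnorm(100)
  res <- prioritize_and_test(y, G, cbind(rnorm(100)),
                             prioritization_config(1e-6, panel_size = 5))
  expect_equal(nrow(res$tests), 0)
  expect_equal(res$n_prioritized, 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_prioritization_tsv(res, path)
  expect_identical(names(read.delim(path)),
                   c("snp", "partner", "levene_p", "beta3_hat", "se",
                     "t_stat", "interaction_p", "threshold", "significant"))
})
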