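# Independent brute-force oracles, coded as directly as possible from the
# defining formulas, for cross-checking the package implementations.

# Levene W by literal transcription: Z_ij = |y_ij - mean_i|, ANOVA of the Z's.
oracle_levene_w <- function(y, group) {
  groups <- split(y, group)
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  N <- sum(lengths(groups))
  z <- lapply(groups, function(v) abs(v - mean(v)))
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- mean(unlist(z))
  num <- sum(lengths(groups) * (zbar_i - zbar)^2)
  den <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                    numeric(1)))
  (N - k) / (k - 1) * num / den
}

# OLS of y on [1, g, c, g*c] via explicit normal equations; returns the
# interaction coefficient, its SE and two-sided t-test p-value.
oracle_ols_interaction <- function(y, g, c_) {
  X <- cbind(1, g, c_, g * c_)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - 4
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(xtx_inv))
  t3 <- beta[4] / se[4]
  list(beta3 = unname(beta[4]), se = unname(se[4]),
       p = unname(2 * pt(abs(t3), df, lower.tail = FALSE)))
}

# Exact HWE p-value by enumeration: conditional probabilities of every
# attainable heterozygote count obtained by normalizing multinomial HWE
# densities (any HWE allele frequency gives the same conditional law).
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n - n_a
  if (min(n_a, n_A) == 0) return(1)
  het <- seq(min(n_a, n_A) %% 2, min(n_a, n_A), by = 2)
  w <- vapply(het, function(h)
    dmultinom(c((n_A - h) / 2, h, (n_a - h) / 2),
              prob = c(0.49, 0.42, 0.09)), numeric(1))
  w <- w / sum(w)
  sum(w[w <= w[match(n_Aa, het)] * (1 + 1e-12)])
}

# Shared fixture: a small deterministic interaction dataset.
make_fixed_dataset <- function(n = 20) {
  g <- rep(c(-0.4, 0.6, 1.6, -0.4, 0.6), length.out = n)
  c_ <- sin(seq_len(n))
  y <- 0.2 + 0.1 * g + 0.3 * c_ + 0.25 * g * c_ +
    cos(seq_len(n) * 2)  # deterministic "noise"
  list(y = y, g = g, c_ = c_)
}
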