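#' Levene's test of equality of variance (mean-centered)
#'
#' Tests the null hypothesis that \eqn{k} groups share a common variance.
#' With \eqn{Z_{ij} = |y_{ij} - \bar y_i|} (absolute deviations from the
#' group mean), the statistic is
#' \deqn{W = \frac{N-k}{k-1} \cdot
#'       \frac{\sum_i N_i (\bar Z_i - \bar Z)^2}
#'            {\sum_i \sum_j (Z_{ij} - \bar Z_i)^2},}
#' referred to the \eqn{F_{k-1,\,N-k}} distribution (upper tail). The
#' mean-centered form is used throughout, not the median-centered
#' Brown-Forsythe variant. Levene's test is far less sensitive to
#' non-normality than Bartlett's test, which makes it usable as a
#' genome-wide screen on real traits.
#'
#' Individuals with missing trait or group label are dropped pairwise.
#' Groups that are empty after deletion do not count towards \eqn{k};
#' singleton groups are retained (they contribute zero to the denominator).
#' A monomorphic grouping (\eqn{k < 2}) or a zero denominator yields a
#' degenerate result (`degenerate = TRUE`, `NA` statistic and p-value)
#' rather than an error, since both arise routinely in genome scans.
#'
#' @param y Numeric trait values.
#' @param group Group labels (any type coercible to factor), same length
#'   as `y`.
#' @return An object of classes `"levene_test"` and `"htest"` with
#'   `statistic` (W), `parameter` (df1 = k-1, df2 = N-k), `p.value`,
#'   plus `k`, `group_sizes`, `group_variances`, `n_used` and a
#'   `degenerate` flag (with `reason` when degenerate).
#' @examples
#' levene_test(c(1, 3, 5, 2, 6), rep(c("a", "b"), c(3, 2)))
#' @export
levene_test <- function(y, group) {
  if (length(y) != length(group))
    stop("'y' and 'group' must have the same length", call. = FALSE)
  keep <- !is.na(y) & !is.na(group)
  y <- as.numeric(y[keep])
  f <- factor(group[keep])
  f <- droplevels(f)
  gi <- as.integer(f)
  k <- nlevels(f)
  res <- levene_core(y, gi, k)

  sizes <- tabulate(gi, k)
  vars <- rep(NA_real_, k)
  if (length(y)) {
    ssq <- rowsum_vec(y^2, gi, k)
    sm <- rowsum_vec(y, gi, k)
    vars <- ifelse(sizes > 1, (ssq - sm^2 / sizes) / (sizes - 1), NA_real_)
  }
  names(sizes) <- names(vars) <- levels(f)

  structure(
    c(res,
      list(k = k, group_sizes = sizes, group_variances = vars,
           n_used = length(y),
           method = "Levene's test of equality of variance (mean-centered)",
           data.name = paste(deparse1(substitute(y)), "by",
                             deparse1(substitute(group))))),
    class = c("levene_test", "htest"))
}

## Core W computation on an integer group index 1..k (no validation).
## Returned fields follow the htest convention.
levene_core <- function(y, gi, k) {
  N <- length(y)
  if (k < 2L || N - k < 1L)
    return(degenerate_levene(if (k < 2L) "fewer than 2 non-empty groups"
                             else "N - k < 1"))
  ni <- tabulate(gi, k)
  mi <- rowsum_vec(y, gi, k) / ni
  z <- abs(y - mi[gi])
  zbar_i <- rowsum_vec(z, gi, k) / ni
  zbar <- sum(z) / N
  num <- sum(ni * (zbar_i - zbar)^2)
  den <- sum((z - zbar_i[gi])^2)
  if (den <= 0) {
    if (num <= 0)
      return(degenerate_levene("no variation in absolute deviations"))
    return(list(statistic = c(W = Inf),
                parameter = c(df1 = k - 1, df2 = N - k),
                p.value = 0, degenerate = FALSE, reason = NA_character_))
  }
  W <- (N - k) / (k - 1) * num / den
  list(statistic = c(W = W),
       parameter = c(df1 = k - 1, df2 = N - k),
       p.value = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
       degenerate = FALSE, reason = NA_character_)
}

degenerate_levene <- function(reason) {
  list(statistic = c(W = NA_real_),
       parameter = c(df1 = NA_real_, df2 = NA_real_),
       p.value = NA_real_, degenerate = TRUE, reason = reason)
}

## rowsum() returning a plain length-k vector (zero for empty groups).
rowsum_vec <- function(x, gi, k) {
  out <- numeric(k)
  rs <- rowsum(x, gi)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

## Fast path for simulation loops: complete (no NA) allele counts in 0:2.
## Compacts absent genotype classes before delegating to levene_core.
levene_counts_fast <- function(y, counts) {
  present <- tabulate(counts + 1L, 3L) > 0L
  map <- cumsum(present)
  levene_core(y, map[counts + 1L], sum(present))
}

#' Levene's test across the genotype classes of a SNP
#'
#' Groups individuals by additive genotype (allele counts 0, 1, 2), drops
#' individuals missing either the trait or the genotype, and applies
#' [levene_test()]. Genotype classes absent from the sample reduce the
#' number of groups \eqn{k} (a SNP with no minor-allele homozygotes is
#' tested with \eqn{k = 2}); a monomorphic SNP gives a degenerate result.
#' This is the per-SNP screening statistic of variance prioritization: an
#' interaction with any (possibly unmeasured) covariate inflates the trait
#' variance differentially across genotypes.
#'
#' @param y Numeric trait values.
#' @param genotype Allele counts in \{0, 1, 2\} with `NA` for missing calls.
#' @return A `"levene_test"` object; `group_sizes` and `group_variances`
#'   are named by allele count ("0", "1", "2") with `NA` entries for
#'   genotype classes absent from the sample.
#' @export
levene_by_genotype <- function(y, genotype) {
  if (length(y) != length(genotype))
    stop("'y' and 'genotype' must have the same length", call. = FALSE)
  bad <- !is.na(genotype) & !genotype %in% c(0, 1, 2)
  if (any(bad))
    stop("'genotype' must contain allele counts in {0, 1, 2} or NA",
         call. = FALSE)
  res <- levene_test(y, genotype)
  sizes <- stats::setNames(rep(NA_real_, 3), c("0", "1", "2"))
  vars <- sizes
  sizes[names(res$group_sizes)] <- res$group_sizes
  vars[names(res$group_variances)] <- res$group_variances
  res$group_sizes <- sizes
  res$group_variances <- vars
  res$data.name <- "trait by genotype class"
  res
}
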