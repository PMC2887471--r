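#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype counts of a biallelic SNP: given
#' the observed minor-allele count, the probability of each possible
#' heterozygote count under Hardy-Weinberg equilibrium is
#' \deqn{P(n_{Aa} \mid n_A, N) =
#'   \frac{N!\, 2^{n_{Aa}}\, n_A!\, n_a!}
#'        {n_{AA}!\, n_{Aa}!\, n_{aa}!\, (2N)!},}
#' and the p-value sums the probabilities of all heterozygote counts no
#' more probable than the observed one. A monomorphic sample has a single
#' attainable configuration and returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return Exact p-value (standard, not mid-p).
#' @examples
#' hwe_exact_test(n_AA = 40, n_Aa = 45, n_aa = 15)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual required", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa   # minor-allele count (label irrelevant by symmetry)
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)
  ## attainable heterozygote counts share the parity of the rare-allele count
  het <- seq(rare %% 2, rare, by = 2)
  logp <- lgamma(n + 1) + het * log(2) +
    lgamma(n_a + 1) + lgamma(n_A + 1) - lgamma(2 * n + 1) -
    lgamma((n_a - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((n_A - het) / 2 + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Quality-control thresholds for a genotype panel
#'
#' @param min_snp_call_rate Minimum SNP call rate among retained samples
#'   (default 0.90: SNPs with call rate below 90\% are excluded).
#' @param max_sample_missing Maximum per-sample missing-genotype fraction
#'   (default 0.02).
#' @param hwe_p_floor Exact Hardy-Weinberg p-value below which a SNP is
#'   excluded (default 1e-6).
#' @param min_maf Minor allele frequency at or below which a SNP is
#'   excluded (exclusive bound; default 0.01, i.e. MAF > 1\% retained).
#' @return An object of class `"qc_config"`.
#' @export
qc_config <- function(min_snp_call_rate = 0.90, max_sample_missing = 0.02,
                      hwe_p_floor = 1e-6, min_maf = 0.01) {
  vals <- c(min_snp_call_rate, max_sample_missing, hwe_p_floor, min_maf)
  stopifnot(all(vals > 0), all(vals < 1))
  structure(list(min_snp_call_rate = min_snp_call_rate,
                 max_sample_missing = max_sample_missing,
                 hwe_p_floor = hwe_p_floor, min_maf = min_maf),
            class = "qc_config")
}

#' Filter a genotype panel by sample and SNP quality
#'
#' Applies the standard GWAS quality-control sequence, in order:
#' \enumerate{
#'   \item drop samples whose missing-genotype fraction exceeds
#'     `max_sample_missing`;
#'   \item among retained samples, drop SNPs with call rate below
#'     `min_snp_call_rate`;
#'   \item drop SNPs whose exact Hardy-Weinberg p-value (computed on
#'     retained samples) is below `hwe_p_floor`;
#'   \item drop SNPs with minor allele frequency at or below `min_maf`.
#' }
#' The filter is idempotent: running it on its own output removes nothing.
#'
#' @param genotypes Allele-count matrix (individuals x SNPs, 0/1/2/NA).
#' @param config A [qc_config()].
#' @return A list of class `"qc_report"`: `genotypes` (filtered matrix),
#'   `snps` (per-SNP data frame: id, call_rate, maf, hwe_p, pass,
#'   reason), `samples` (per-sample data frame: id, missing_rate, pass),
#'   `config`.
#' @export
qc_filter <- function(genotypes, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))

  sample_missing <- rowMeans(is.na(genotypes))
  sample_pass <- sample_missing <= config$max_sample_missing
  samples <- data.frame(id = rownames(genotypes),
                        missing_rate = sample_missing,
                        pass = sample_pass, row.names = NULL)
  G <- genotypes[sample_pass, , drop = FALSE]
  n_kept <- nrow(G)

  ids <- colnames(G)
  call_rate <- if (n_kept) colMeans(!is.na(G)) else rep(0, ncol(G))
  n_het <- colSums(G == 1L, na.rm = TRUE)
  n_hom2 <- colSums(G == 2L, na.rm = TRUE)
  n_obs <- colSums(!is.na(G))
  n_hom1 <- n_obs - n_het - n_hom2
  freq <- ifelse(n_obs > 0, (n_het + 2 * n_hom2) / (2 * n_obs), NA_real_)
  maf <- pmin(freq, 1 - freq)
  hwe_p <- vapply(seq_along(ids), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    hwe_exact_test(n_hom1[j], n_het[j], n_hom2[j])
  }, numeric(1))

  reason <- rep(NA_character_, length(ids))
  fail_call <- call_rate < config$min_snp_call_rate
  fail_hwe <- !fail_call & !is.na(hwe_p) & hwe_p < config$hwe_p_floor
  fail_maf <- !fail_call & !fail_hwe &
    (is.na(maf) | maf <= config$min_maf)
  reason[fail_call] <- "call_rate"
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  pass <- is.na(reason)

  snps <- data.frame(id = ids, call_rate = call_rate, maf = maf,
                     hwe_p = hwe_p, pass = pass, reason = reason,
                     row.names = NULL)
  structure(list(genotypes = G[, pass, drop = FALSE], snps = snps,
                 samples = samples, config = config),
            class = "qc_report")
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d samples retained; %d/%d SNPs retained\n",
              sum(x$samples$pass), nrow(x$samples),
              sum(x$snps$pass), nrow(x$snps)))
  drops <- table(x$snps$reason)
  if (length(drops))
    cat("  SNP exclusions:",
        paste(sprintf("%s = %d", names(drops), drops), collapse = ", "), "\n")
  invisible(x)
}

#' Expected/observed quantile data for p-value QQ plots
#'
#' Sorted p-values paired with their uniform expected quantiles
#' \eqn{i/(m+1)} and pointwise confidence bands from the beta distribution
#' of uniform order statistics (the i-th of m uniforms is
#' Beta(i, m - i + 1)).
#'
#' @param p Vector of p-values (`NA` dropped).
#' @param band Pointwise coverage (default 0.95).
#' @return Data frame with `observed`, `expected`, `band_lo`, `band_hi`,
#'   sorted ascending.
#' @export
qq_data <- function(p, band = 0.95) {
  p <- sort(p[!is.na(p)])
  m <- length(p)
  if (m == 0L)
    return(data.frame(observed = numeric(0), expected = numeric(0),
                      band_lo = numeric(0), band_hi = numeric(0)))
  i <- seq_len(m)
  a <- (1 - band) / 2
  data.frame(observed = p, expected = i / (m + 1),
             band_lo = stats::qbeta(a, i, m - i + 1),
             band_hi = stats::qbeta(1 - a, i, m - i + 1))
}

#' Genome-wide Levene scan of a quantitative trait
#'
#' Applies [levene_by_genotype()] to every SNP of a (QC'd) genotype panel,
#' flags SNPs below the genome-wide threshold `scan_alpha`, and attaches
#' QQ-plot data for the p-value distribution. Any trait transformation
#' (e.g. a log transform for a right-skewed biomarker) is the caller's
#' responsibility.
#'
#' @param y Trait values, one per row of `genotypes`.
#' @param genotypes Allele-count matrix (individuals x SNPs).
#' @param scan_alpha Genome-wide significance threshold for the Levene
#'   p-value (default 0.05 / 340,000).
#' @return An object of class `"levene_scan"`: list with `snps` (data
#'   frame: id, maf, n_used, per-genotype counts `n0/n1/n2` and variances
#'   `var0/var1/var2`, `W`, `levene_p`, `degenerate`, `significant`),
#'   `qq` ([qq_data()] of the non-degenerate p-values), `scan_alpha`.
#' @export
genome_scan_levene <- function(y, genotypes, scan_alpha = 0.05 / 340000) {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  if (length(y) != nrow(genotypes))
    stop("'y' must have one value per genotype row", call. = FALSE)
  rows <- lapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    res <- levene_by_genotype(y, g)
    freq <- mean(g, na.rm = TRUE) / 2
    data.frame(id = colnames(genotypes)[j],
               maf = min(freq, 1 - freq),
               n_used = res$n_used,
               n0 = res$group_sizes[["0"]], n1 = res$group_sizes[["1"]],
               n2 = res$group_sizes[["2"]],
               var0 = res$group_variances[["0"]],
               var1 = res$group_variances[["1"]],
               var2 = res$group_variances[["2"]],
               W = unname(res$statistic), levene_p = res$p.value,
               degenerate = res$degenerate, row.names = NULL)
  })
  snps <- do.call(rbind, rows)
  snps$significant <- !is.na(snps$levene_p) & snps$levene_p < scan_alpha
  structure(list(snps = snps, qq = qq_data(snps$levene_p),
                 scan_alpha = scan_alpha),
            class = "levene_scan")
}

#' @export
#' @method print levene_scan
print.levene_scan <- function(x, ...) {
  cat(sprintf("Levene variance scan: %d SNPs (%d degenerate), threshold %.3g\n",
              nrow(x$snps), sum(x$snps$degenerate), x$scan_alpha))
  sig <- x$snps[x$snps$significant, , drop = FALSE]
  cat(sprintf("  %d genome-wide-significant SNP(s)\n", nrow(sig)))
  if (nrow(sig))
    print(sig[c("id", "maf", "var0", "var1", "var2", "levene_p")],
          row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
#' @method plot levene_scan
plot.levene_scan <- function(x, ...) {
  q <- x$qq
  if (!nrow(q)) stop("no p-values to plot")
  graphics::plot(-log10(q$expected), -log10(q$observed), pch = 16, cex = 0.6,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::lines(-log10(q$expected), -log10(q$band_lo), lty = 2)
  graphics::lines(-log10(q$expected), -log10(q$band_hi), lty = 2)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Levene test after adjusting the trait for a known interaction
#'
#' Regresses the trait on the genotype, a covariate and their product, then
#' re-applies [levene_by_genotype()] to the residuals. If the named
#' interaction is the only source of variance heterogeneity at the SNP, the
#' adjusted p-value is null-distributed; residual heterogeneity indicates
#' that the interaction explains only part of the variance inequality
#' (e.g. further unmeasured interacting covariates).
#'
#' @param y Trait values.
#' @param genotype Allele counts in \{0, 1, 2\} (NA allowed).
#' @param covariate Covariate tested for interaction.
#' @return A `"levene_test"` object on the residuals, with attribute
#'   `"fit"` carrying the [interaction_regression()] used for adjustment.
#' @export
levene_adjusted <- function(y, genotype, covariate) {
  keep <- !(is.na(y) | is.na(genotype) | is.na(covariate))
  y <- y[keep]; genotype <- genotype[keep]; covariate <- covariate[keep]
  freq <- mean(genotype) / 2
  if (freq <= 0 || freq >= 1)
    stop("monomorphic SNP: adjustment undefined", call. = FALSE)
  g <- genotype - 2 * freq
  fit <- interaction_regression(y, g, covariate)
  if (fit$degenerate)
    stop("adjustment regression degenerate: ", fit$reason, call. = FALSE)
  out <- levene_by_genotype(fit$residuals, genotype)
  attr(out, "fit") <- fit
  out
}
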