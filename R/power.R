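#' Define a Monte-Carlo power experiment
#'
#' Fixes the generating [trait_model()], the per-replicate sample size, the
#' replicate count and a root seed. Each replicate simulates one causal SNP
#' (plus covariate or partner SNP); the surrounding SNP panel enters only
#' through the multiple-testing denominators of [corrected_threshold()],
#' which makes genome-scale power experiments runnable at desk scale.
#'
#' @param model A `trait_model`.
#' @param n Individuals per replicate (default 15,000, a typical
#'   biobank-scale GWAS arm).
#' @param reps Number of replicates.
#' @param seed Integer root seed; per-replicate seeds are spawned from it,
#'   so the same experiment always reproduces the same replicates.
#' @return An object of class `"power_experiment"`.
#' @export
power_experiment <- function(model, n = 15000, reps = 1000, seed = NULL) {
  stopifnot(inherits(model, "trait_model"), reps >= 1)
  check_n(n)
  structure(list(model = model, n = n, reps = as.integer(reps), seed = seed),
            class = "power_experiment")
}

#' Run the replicates of a power experiment once, caching test statistics
#'
#' Simulates every replicate of the experiment and records, per replicate,
#' the Levene p-value of the causal SNP (both SNPs in the gene-by-gene
#' design) and the interaction-regression p-value of the causal pair.
#' All power summaries ([power_levene_screen()],
#' [power_exhaustive_regression()], [power_variance_prioritization()])
#' accept this object, so different thresholds are evaluated on common
#' random numbers. Degenerate replicates (monomorphic genotype draws) carry
#' `NA` p-values and count as non-rejections.
#'
#' @param exp A [power_experiment()].
#' @return An object of class `"power_replicates"`: list with `levene_p1`,
#'   `levene_p2` (`NA` column in gene-by-environment mode),
#'   `interaction_p`, and the experiment.
#' @export
power_replicates <- function(exp) {
  stopifnot(inherits(exp, "power_experiment"))
  gxg <- exp$model$covariate == "snp"
  sim <- if (gxg) simulate_gxg else simulate_gxe
  seeds <- spawn_seeds(exp$seed, exp$reps)
  p_lev1 <- p_lev2 <- p_int <- rep(NA_real_, exp$reps)
  for (r in seq_len(exp$reps)) {
    d <- sim(exp$model, exp$n, seed = seeds[[r]])
    p_lev1[r] <- levene_counts_fast(d$y, d$counts1)$p.value
    if (gxg) p_lev2[r] <- levene_counts_fast(d$y, d$counts2)$p.value
    p_int[r] <- interaction_regression(d$y, d$g1, d$covariate)$p_value
  }
  structure(list(levene_p1 = p_lev1, levene_p2 = p_lev2,
                 interaction_p = p_int, experiment = exp),
            class = "power_replicates")
}

as_replicates <- function(x) {
  if (inherits(x, "power_replicates")) x else power_replicates(x)
}

power_result <- function(hits, reps, condition, threshold) {
  power <- mean(hits)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / reps),
                 reps_used = reps, condition = condition,
                 threshold = threshold),
            class = "power_result")
}

#' @export
#' @method print power_result
print.power_result <- function(x, ...) {
  cat(sprintf("%s: power = %.4f (MC SE %.4f, %d replicates)\n",
              x$condition, x$power, x$mc_se, x$reps_used))
  invisible(x)
}

#' Power of the Levene screen
#'
#' Fraction of replicates in which the causal SNP's Levene p-value falls
#' below `alpha` (gene-by-environment), or in which *either* causal SNP
#' passes (gene-by-gene).
#'
#' @param exp A [power_experiment()] or cached [power_replicates()].
#' @param alpha Screening threshold.
#' @return A `"power_result"` with the rejection fraction and its binomial
#'   Monte-Carlo standard error.
#' @export
power_levene_screen <- function(exp, alpha) {
  r <- as_replicates(exp)
  hit <- screen_pass(r, alpha)
  power_result(hit, r$experiment$reps,
               sprintf("Levene screen at alpha = %g", alpha), alpha)
}

screen_pass <- function(r, alpha) {
  h1 <- !is.na(r$levene_p1) & r$levene_p1 < alpha
  if (r$experiment$model$covariate == "snp") {
    h2 <- !is.na(r$levene_p2) & r$levene_p2 < alpha
    h1 | h2
  } else h1
}

#' Power of the exhaustive interaction-regression search
#'
#' Fraction of replicates in which the causal pair's interaction p-value
#' falls below the per-test threshold `alpha` (typically the exhaustive
#' Bonferroni threshold: `0.05/M` for gene-by-environment, `0.05/M^2` for
#' all SNP pairs).
#'
#' @inheritParams power_levene_screen
#' @param alpha Per-test significance threshold.
#' @return A `"power_result"`.
#' @export
power_exhaustive_regression <- function(exp, alpha) {
  r <- as_replicates(exp)
  hit <- !is.na(r$interaction_p) & r$interaction_p < alpha
  power_result(hit, r$experiment$reps,
               sprintf("exhaustive regression at alpha = %g", alpha), alpha)
}

#' Power of two-step variance prioritization over a threshold grid
#'
#' For each Levene screening threshold in `alpha_grid`, a replicate counts
#' as a success when the causal SNP passes the screen (either causal SNP in
#' gene-by-gene mode) *and* the interaction p-value of the causal pair
#' falls below [corrected_threshold()] evaluated at that screening
#' threshold. `alpha_levene = 1` makes the screen vacuous and reproduces
#' [power_exhaustive_regression()] at the exhaustive threshold exactly
#' (same replicates).
#'
#' @inheritParams power_levene_screen
#' @param config A [prioritization_config()]; its `alpha_levene` is
#'   replaced by each grid value in turn.
#' @param alpha_grid Levene thresholds to evaluate (default: 20 log-spaced
#'   values spanning 1e-7 to 1).
#' @return An object of class `"power_curve"`: data frame with columns
#'   `alpha_levene`, `threshold`, `power`, `mc_se`, plus attributes
#'   `experiment` and `config`.
#' @export
power_variance_prioritization <- function(exp, config,
                                          alpha_grid = 10^seq(-7, 0,
                                                              length.out = 20)) {
  stopifnot(inherits(config, "prioritization_config"))
  r <- as_replicates(exp)
  reps <- r$experiment$reps
  rows <- lapply(alpha_grid, function(a) {
    cfg <- config
    cfg$alpha_levene <- a
    thr <- corrected_threshold(cfg)
    hit <- screen_pass(r, a) & !is.na(r$interaction_p) & r$interaction_p < thr
    p <- mean(hit)
    data.frame(alpha_levene = a, threshold = thr, power = p,
               mc_se = sqrt(p * (1 - p) / reps))
  })
  out <- do.call(rbind, rows)
  attr(out, "experiment") <- r$experiment
  attr(out, "config") <- config
  class(out) <- c("power_curve", "data.frame")
  out
}

#' @export
#' @method plot power_curve
plot.power_curve <- function(x, ...) {
  graphics::plot(x$alpha_levene, x$power, log = "x", type = "b", pch = 16,
                 xlab = "Levene screening threshold (alpha_L)",
                 ylab = "Power", ylim = c(0, max(x$power, 0.05) * 1.1), ...)
  graphics::arrows(x$alpha_levene, pmax(0, x$power - 1.96 * x$mc_se),
                   x$alpha_levene, x$power + 1.96 * x$mc_se,
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Null-independence diagnostic of the two-step procedure
#'
#' Under the null of no interaction (\eqn{\beta_3 = 0}) the Levene
#' statistic and the interaction-regression estimate are independent, so
#' selecting replicates by Levene p-value must leave the interaction
#' p-values Uniform(0, 1). This function simulates `reps` null replicates,
#' keeps those with Levene p below `levene_select`, and returns their
#' sorted interaction p-values with uniform expected quantiles, pointwise
#' beta-order-statistic confidence bands, and a Kolmogorov-Smirnov
#' uniformity p-value.
#'
#' @param model A `trait_model` with `beta3 = 0` (enforced).
#' @param n Individuals per replicate.
#' @param reps Number of null replicates.
#' @param levene_select Screening threshold used for selection.
#' @param seed Integer root seed.
#' @param band Pointwise band coverage (default 0.95).
#' @return An object of class `"independence_diagnostic"`: list with
#'   `p_selected` (sorted), `expected`, `band_lo`, `band_hi`,
#'   `ks_p`, `n_selected`, `reps`, `levene_select`; `empty = TRUE` when no
#'   replicate passes selection.
#' @export
independence_diagnostic <- function(model, n, reps, levene_select = 0.05,
                                    seed = NULL, band = 0.95) {
  stopifnot(inherits(model, "trait_model"))
  if (model$beta3 != 0)
    stop("the independence diagnostic is defined under beta3 = 0",
         call. = FALSE)
  exp <- power_experiment(model, n = n, reps = reps, seed = seed)
  r <- power_replicates(exp)
  keep <- screen_pass(r, levene_select) & !is.na(r$interaction_p)
  p_sel <- sort(r$interaction_p[keep])
  m <- length(p_sel)
  if (m == 0L)
    return(structure(list(empty = TRUE, n_selected = 0L, reps = reps,
                          levene_select = levene_select),
                     class = "independence_diagnostic"))
  i <- seq_len(m)
  a <- (1 - band) / 2
  ks <- stats::ks.test(p_sel, "punif")
  structure(list(empty = FALSE, p_selected = p_sel,
                 expected = i / (m + 1),
                 band_lo = stats::qbeta(a, i, m - i + 1),
                 band_hi = stats::qbeta(1 - a, i, m - i + 1),
                 ks_p = ks$p.value, n_selected = m, reps = reps,
                 levene_select = levene_select),
            class = "independence_diagnostic")
}

#' @export
#' @method print independence_diagnostic
print.independence_diagnostic <- function(x, ...) {
  if (x$empty) {
    cat("Independence diagnostic: no replicate passed selection\n")
    return(invisible(x))
  }
  cat(sprintf("Independence diagnostic: %d/%d null replicates with Levene p < %g\n",
              x$n_selected, x$reps, x$levene_select))
  cat(sprintf("  KS uniformity p-value of selected interaction p-values: %.4g\n",
              x$ks_p))
  invisible(x)
}

#' @export
#' @method plot independence_diagnostic
plot.independence_diagnostic <- function(x, ...) {
  if (x$empty) stop("nothing to plot: no replicate passed selection")
  ex <- -log10(x$expected)
  graphics::plot(ex, -log10(x$p_selected), pch = 16, cex = 0.6,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::lines(ex, -log10(x$band_lo), lty = 2)
  graphics::lines(ex, -log10(x$band_hi), lty = 2)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Analytic approximation to interaction-regression power
#'
#' Approximates the power of the two-sided interaction t-test at level
#' `alpha` using the noncentral F distribution: with \eqn{f^2} the ratio of
#' interaction-explained variance to residual (noise) variance from
#' [variance_partition()], the test statistic is approximately
#' \eqn{F(1, n - 4)} with noncentrality \eqn{n f^2}. It treats the
#' regressors' moments as fixed at their population values, so it is an
#' approximation, used as an independent cross-check of the Monte-Carlo
#' engine rather than as a replacement for it.
#'
#' @param model A `trait_model`.
#' @param n Sample size.
#' @param alpha Two-sided significance level.
#' @return Approximate power in [0, 1].
#' @export
analytic_power_oracle <- function(model, n, alpha) {
  stopifnot(inherits(model, "trait_model"))
  vp <- variance_partition(model)
  f2 <- vp$components[["interaction"]] / vp$components[["noise"]]
  ncp <- n * f2
  crit <- stats::qf(alpha, 1, n - 4, lower.tail = FALSE)
  stats::pf(crit, 1, n - 4, ncp = ncp, lower.tail = FALSE)
}
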