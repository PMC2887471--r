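#' Linear-regression test of a genotype-covariate interaction
#'
#' Fits the ordinary least-squares model
#' \eqn{y = \beta_0 + \beta_1 g + \beta_2 c + \beta_3 g c + \epsilon}
#' and tests \eqn{H_0: \beta_3 = 0} with the two-sided t-test on the
#' product-term coefficient (\eqn{n - 4} degrees of freedom). This is the
#' confirmatory second step of variance prioritization; its p-value is
#' independent of the Levene screen under the null of no interaction, which
#' is what keeps the two-step procedure's type-I error valid.
#'
#' Individuals with any missing value are dropped pairwise. A rank-deficient
#' design (monomorphic SNP, constant covariate, or covariate identical to
#' the genotype) yields a degenerate result rather than an error.
#'
#' @param y Trait values.
#' @param g Centered genotype (use [center_genotype()] with the sample
#'   allele frequency when analysing data).
#' @param c_ Covariate values (environmental measure or partner genotype).
#' @return An object of class `"interaction_fit"`: `beta3_hat`, `se`,
#'   `t_stat`, `p_value`, `n_used`, full `coefficients`, `residuals`,
#'   `df_residual` and a `degenerate` flag.
#' @examples
#' d <- simulate_gxe(trait_model(0.2, beta2 = 0.3, beta3 = 0.2), 500, seed = 2)
#' interaction_regression(d$y, d$g1, d$covariate)
#' @export
interaction_regression <- function(y, g, c_) {
  n_in <- length(y)
  if (length(g) != n_in || length(c_) != n_in)
    stop("'y', 'g' and 'c_' must have the same length", call. = FALSE)
  keep <- !(is.na(y) | is.na(g) | is.na(c_))
  y <- as.numeric(y[keep]); g <- as.numeric(g[keep]); c_ <- as.numeric(c_[keep])
  n <- length(y)
  if (n <= 4L)
    return(degenerate_interaction(n, "fewer than 5 complete observations"))
  X <- cbind(`(Intercept)` = 1, g = g, c = c_, `g:c` = g * c_)
  A <- crossprod(X)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch)))
    return(degenerate_interaction(n, "rank-deficient design"))
  Ainv <- chol2inv(ch)
  beta <- drop(Ainv %*% crossprod(X, y))
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  df <- n - 4L
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(Ainv))
  t3 <- unname(beta[4L] / se[4L])
  structure(list(beta3_hat = unname(beta[4L]), se = unname(se[4L]),
                 t_stat = unname(t3),
                 p_value = 2 * stats::pt(abs(t3), df, lower.tail = FALSE),
                 n_used = n, coefficients = beta,
                 se_all = stats::setNames(se, names(beta)),
                 residuals = res, df_residual = df, sigma = sqrt(sigma2),
                 degenerate = FALSE, reason = NA_character_),
            class = "interaction_fit")
}

degenerate_interaction <- function(n, reason) {
  structure(list(beta3_hat = NA_real_, se = NA_real_, t_stat = NA_real_,
                 p_value = NA_real_, n_used = n, coefficients = NULL,
                 se_all = NULL, residuals = NULL, df_residual = NA_integer_,
                 sigma = NA_real_, degenerate = TRUE, reason = reason),
            class = "interaction_fit")
}

#' @export
#' @method print interaction_fit
print.interaction_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Interaction regression: degenerate (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Interaction regression (OLS, y ~ g * c)\n")
  cat(sprintf("  beta3 = %.6g (SE %.4g), t = %.4g on %d df, p = %.4g, n = %d\n",
              x$beta3_hat, x$se, x$t_stat, x$df_residual, x$p_value, x$n_used))
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) object$coefficients

#' @export
residuals.interaction_fit <- function(object, ...) object$residuals

#' Configuration of the two-step variance-prioritization procedure
#'
#' Bundles the Levene screening threshold \eqn{\alpha_L}, the assumed SNP
#' panel size \eqn{M}, the interaction mode, and the family-wise error
#' budget. The second-step Bonferroni correction is scaled by the screen:
#' only a fraction \eqn{\alpha_L} of a null panel is expected to be
#' prioritized, so the effective number of interaction tests is
#' \eqn{\alpha_L M} per covariate (gene-by-environment) or
#' \eqn{\alpha_L M^2} (gene-by-gene, where each prioritized SNP is tested
#' against *all* panel SNPs, not only prioritized ones).
#'
#' @param alpha_levene Screening threshold \eqn{\alpha_L} in (0, 1];
#'   `alpha_levene = 1` makes the screen vacuous and reproduces the
#'   exhaustive-search thresholds.
#' @param panel_size Assumed panel size \eqn{M} (default 340,000, the scale
#'   of a genome-wide SNP array after quality control).
#' @param mode `"gxe"` or `"gxg"`.
#' @param fwer Family-wise error rate to control (default 0.05).
#' @param n_covariates Number of declared covariates tested per prioritized
#'   SNP in gene-by-environment mode (enters the correction
#'   multiplicatively; default 1).
#' @return An object of class `"prioritization_config"`.
#' @export
prioritization_config <- function(alpha_levene, panel_size = 340000,
                                  mode = c("gxe", "gxg"), fwer = 0.05,
                                  n_covariates = 1) {
  mode <- match.arg(mode)
  stopifnot(alpha_levene > 0, alpha_levene <= 1, panel_size >= 1,
            fwer > 0, fwer < 1, n_covariates >= 1)
  structure(list(alpha_levene = alpha_levene, panel_size = panel_size,
                 mode = mode, fwer = fwer, n_covariates = n_covariates),
            class = "prioritization_config")
}

#' @export
#' @method print prioritization_config
print.prioritization_config <- function(x, ...) {
  cat(sprintf("Variance prioritization: mode %s, alpha_L = %g, M = %g, FWER = %g\n",
              x$mode, x$alpha_levene, x$panel_size, x$fwer))
  cat(sprintf("  second-step significance threshold: %.3g\n",
              corrected_threshold(x)))
  invisible(x)
}

#' Second-step significance threshold after variance prioritization
#'
#' Returns the per-test p-value threshold for the interaction regression:
#' `fwer / (alpha_levene * M * n_covariates)` in gene-by-environment mode
#' and `fwer / (alpha_levene * M^2)` in gene-by-gene mode (ordered pairs,
#' since prioritized SNPs are tested against the whole panel). With
#' `alpha_levene = 1` these collapse to the exhaustive Bonferroni
#' thresholds, e.g. 0.05/340,000 = 1.5e-7 and 0.05/340,000^2 = 4.3e-13.
#'
#' @param config A [prioritization_config()].
#' @return A single p-value threshold.
#' @export
corrected_threshold <- function(config) {
  stopifnot(inherits(config, "prioritization_config"))
  m <- config$panel_size
  n_tests <- switch(config$mode,
                    gxe = config$alpha_levene * m * config$n_covariates,
                    gxg = config$alpha_levene * m * m)
  config$fwer / n_tests
}

#' Run the two-step variance-prioritization procedure on a panel
#'
#' Step 1 computes the Levene p-value of every SNP in the (QC'd) genotype
#' matrix and retains those with p below `alpha_levene` (degenerate Levene
#' results — monomorphic SNPs — are never prioritized). Step 2 tests each
#' retained SNP for interaction by OLS: against every supplied covariate
#' column in gene-by-environment mode, or against every *other* SNP of the
#' panel in gene-by-gene mode (a pair in which both members were
#' prioritized is tested once). A result is declared significant when its
#' interaction p-value falls below [corrected_threshold()].
#'
#' Genotypes are centered by their sample allele frequencies before
#' regression.
#'
#' @param y Trait values (one per row of `genotypes`).
#' @param genotypes Allele-count matrix (individuals x SNPs, 0/1/2/NA),
#'   with column names identifying SNPs.
#' @param covariates Numeric matrix or data frame of covariates
#'   (gene-by-environment mode); ignored in gene-by-gene mode.
#' @param config A [prioritization_config()].
#' @return An object of class `"prioritization_result"`: a list with
#'   `levene` (per-SNP screening table), `tests` (data frame: `snp`,
#'   `partner`, `levene_p`, `beta3_hat`, `se`, `t_stat`, `interaction_p`,
#'   `threshold`, `significant`), `config` and `n_prioritized`.
#' @export
prioritize_and_test <- function(y, genotypes, covariates = NULL, config) {
  stopifnot(inherits(config, "prioritization_config"))
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  if (length(y) != nrow(genotypes))
    stop("'y' must have one value per genotype row", call. = FALSE)
  if (config$mode == "gxe") {
    if (is.null(covariates))
      stop("gxe mode requires 'covariates'", call. = FALSE)
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covar", seq_len(ncol(covariates)))
  }

  snp_ids <- colnames(genotypes)
  lev_p <- vapply(seq_along(snp_ids), function(j)
    levene_by_genotype(y, genotypes[, j])$p.value, numeric(1))
  levene_tab <- data.frame(snp = snp_ids, levene_p = lev_p,
                           prioritized = !is.na(lev_p) &
                             lev_p < config$alpha_levene,
                           row.names = NULL)
  sel <- which(levene_tab$prioritized)
  thr <- corrected_threshold(config)

  rows <- list()
  centered <- apply(genotypes, 2, function(gc) {
    ph <- mean(gc, na.rm = TRUE) / 2
    if (is.nan(ph) || ph <= 0 || ph >= 1) return(as.numeric(gc))
    gc - 2 * ph
  })
  if (config$mode == "gxe") {
    for (j in sel) for (v in colnames(covariates)) {
      fit <- interaction_regression(y, centered[, j], covariates[, v])
      rows[[length(rows) + 1L]] <- test_row(snp_ids[j], v, lev_p[j], fit, thr)
    }
  } else {
    seen <- character(0)
    for (j in sel) for (k in seq_along(snp_ids)) {
      if (k == j) next
      key <- paste(sort(c(snp_ids[j], snp_ids[k])), collapse = "\r")
      if (key %in% seen) next   # both-prioritized pair: one hypothesis
      seen <- c(seen, key)
      fit <- interaction_regression(y, centered[, j], centered[, k])
      rows[[length(rows) + 1L]] <- test_row(snp_ids[j], snp_ids[k],
                                            lev_p[j], fit, thr)
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(0), partner = character(0),
               levene_p = numeric(0), beta3_hat = numeric(0),
               se = numeric(0), t_stat = numeric(0),
               interaction_p = numeric(0), threshold = numeric(0),
               significant = logical(0))
  structure(list(levene = levene_tab, tests = tests, config = config,
                 n_prioritized = length(sel)),
            class = "prioritization_result")
}

test_row <- function(snp, partner, lev_p, fit, thr) {
  data.frame(snp = snp, partner = partner, levene_p = lev_p,
             beta3_hat = fit$beta3_hat, se = fit$se, t_stat = fit$t_stat,
             interaction_p = fit$p_value, threshold = thr,
             significant = !fit$degenerate && !is.na(fit$p_value) &&
               fit$p_value < thr,
             row.names = NULL)
}

#' @export
#' @method print prioritization_result
print.prioritization_result <- function(x, ...) {
  cat(sprintf("Variance prioritization (%s): %d/%d SNPs prioritized at alpha_L = %g\n",
              x$config$mode, x$n_prioritized, nrow(x$levene),
              x$config$alpha_levene))
  nsig <- sum(x$tests$significant)
  cat(sprintf("  %d interaction test(s); %d significant below %.3g\n",
              nrow(x$tests), nsig, corrected_threshold(x$config)))
  if (nsig > 0) {
    cat("\nSignificant interactions:\n")
    print(x$tests[x$tests$significant,
                  c("snp", "partner", "levene_p", "beta3_hat",
                    "interaction_p")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.prioritization_result <- function(object, ...) {
  print(object)
  invisible(object$tests)
}

#' @export
as.data.frame.prioritization_result <- function(x, ...) x$tests

#' Write a prioritization results table
#'
#' Writes the step-2 results as a TSV with columns `snp`, `partner`,
#' `levene_p`, `beta3_hat`, `se`, `t_stat`, `interaction_p`, `threshold`,
#' `significant`.
#'
#' @param result A [prioritize_and_test()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prioritization_tsv <- function(result, path) {
  stopifnot(inherits(result, "prioritization_result"))
  utils::write.table(result$tests, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
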