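#' Specify the interaction model for a quantitative trait
#'
#' Constructs the generative model
#' \deqn{Y_i = \beta_0 + \beta_1 G_i + \beta_2 C_i + \beta_3 G_i C_i + \epsilon_i,
#'       \quad \epsilon_i \sim N(0, \sigma^2),}
#' where \eqn{G} is a biallelic SNP in Hardy-Weinberg equilibrium at minor
#' allele frequency `maf`, coded additively and centered so that the
#' population mean genotype is zero (values \eqn{-2p}, \eqn{1-2p},
#' \eqn{2-2p}), and \eqn{C} is either a standard-normal covariate
#' (`covariate = "normal"`, a gene-by-environment design) or a second,
#' independent, centered SNP at frequency `maf2` (`covariate = "snp"`, a
#' gene-by-gene design).
#'
#' Under this model the trait variance conditional on genotype \eqn{g} is
#' \eqn{(\beta_2 + \beta_3 g)^2 Var(C) + \sigma^2}: unequal across genotype
#' classes exactly when \eqn{\beta_3 \neq 0}, and free of \eqn{\beta_1}.
#' That variance signature is what the Levene screen exploits.
#'
#' Instead of supplying `beta3` directly, the interaction strength can be
#' given as `interaction_fraction`, the share of total trait variance
#' attributable to the product term; `beta3` is then calibrated with
#' [beta3_for_fraction()].
#'
#' @param maf Minor allele frequency of the focal SNP, in (0, 0.5].
#' @param beta0,beta1,beta2,beta3 Intercept, marginal genotype effect,
#'   marginal covariate effect, and interaction coefficient (trait units).
#' @param covariate `"normal"` for a N(0,1) environmental covariate,
#'   `"snp"` for a second independent SNP.
#' @param maf2 Allele frequency of the partner SNP (required when
#'   `covariate = "snp"`; defaults to `maf`).
#' @param noise_sd Standard deviation of the residual error (default 1).
#' @param interaction_fraction Optional; if supplied, `beta3` must be left
#'   at its default and is calibrated so the interaction explains this
#'   fraction of total variance.
#' @return An object of class `"trait_model"`.
#' @seealso [variance_by_genotype()], [variance_partition()],
#'   [simulate.trait_model()]
#' @examples
#' m <- trait_model(maf = 0.2, beta2 = 0.3, interaction_fraction = 0.004)
#' variance_partition(m)
#' @export
trait_model <- function(maf, beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                        covariate = c("normal", "snp"), maf2 = NULL,
                        noise_sd = 1, interaction_fraction = NULL) {
  covariate <- match.arg(covariate)
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("'maf' must be a single number in (0, 0.5]", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be positive", call. = FALSE)
  if (covariate == "snp") {
    if (is.null(maf2)) maf2 <- maf
    if (!is.numeric(maf2) || length(maf2) != 1L || maf2 <= 0 || maf2 > 0.5)
      stop("'maf2' must be a single number in (0, 0.5]", call. = FALSE)
  } else if (!is.null(maf2)) {
    stop("'maf2' only applies when covariate = \"snp\"", call. = FALSE)
  }
  for (b in list(beta0, beta1, beta2, beta3))
    if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
      stop("effect coefficients must be single finite numbers", call. = FALSE)

  m <- structure(
    list(maf = maf, maf2 = maf2, beta0 = beta0, beta1 = beta1,
         beta2 = beta2, beta3 = beta3, covariate = covariate,
         noise_sd = noise_sd),
    class = "trait_model")

  if (!is.null(interaction_fraction)) {
    if (beta3 != 0)
      stop("supply either 'beta3' or 'interaction_fraction', not both",
           call. = FALSE)
    m$beta3 <- beta3_for_fraction(interaction_fraction,
                                  maf = maf, beta1 = beta1, beta2 = beta2,
                                  var_c = covariate_variance(m),
                                  noise_sd = noise_sd)
  }
  m
}

#' @export
#' @method print trait_model
print.trait_model <- function(x, ...) {
  kind <- if (x$covariate == "normal") "SNP x covariate (normal C)"
          else sprintf("SNP x SNP (partner MAF %.3g)", x$maf2)
  cat("Quantitative-trait interaction model:", kind, "\n")
  cat(sprintf("  MAF %.3g | beta0 %.4g, beta1 %.4g, beta2 %.4g, beta3 %.4g | noise sd %.3g\n",
              x$maf, x$beta0, x$beta1, x$beta2, x$beta3, x$noise_sd))
  vp <- variance_partition(x)
  cat(sprintf("  variance shares: G %.3g%%, C %.3g%%, GxC %.3g%%, noise %.3g%%\n",
              100 * vp$fractions[["marginal_g"]], 100 * vp$fractions[["covariate"]],
              100 * vp$fractions[["interaction"]], 100 * vp$fractions[["noise"]]))
  invisible(x)
}

## Var(C): 1 for a standardized environmental covariate, 2q(1-q) for a
## centered HWE partner SNP (analytic value, not a sample estimate).
covariate_variance <- function(model) {
  if (model$covariate == "normal") 1 else 2 * model$maf2 * (1 - model$maf2)
}

genotype_variance <- function(p) 2 * p * (1 - p)

#' Center additive genotype calls
#'
#' Shifts allele counts in \{0, 1, 2\} by \eqn{-2p} so that, under
#' Hardy-Weinberg equilibrium at allele frequency `p`, the encoded genotype
#' (\eqn{-2p}, \eqn{1-2p} or \eqn{2-2p}) has population mean 0 and variance
#' \eqn{2p(1-p)}. During simulation the true model frequency is used; when
#' analysing data the sample allele frequency is the natural choice.
#'
#' @param counts Integer allele counts in \{0, 1, 2\}; `NA` allowed and
#'   propagated.
#' @param p Allele frequency in (0, 1) used for centering.
#' @return Numeric vector of centered genotypes with attribute `"maf" = p`.
#' @examples
#' center_genotype(c(0, 1, 2), p = 0.2)
#' @export
center_genotype <- function(counts, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("'p' must be a single number in (0, 1)", call. = FALSE)
  ok <- is.na(counts) | counts %in% c(0, 1, 2)
  if (!all(ok))
    stop("'counts' must be allele counts in {0, 1, 2} (or NA)", call. = FALSE)
  structure(as.numeric(counts) - 2 * p, maf = p)
}

#' Trait variance conditional on genotype
#'
#' Evaluates \eqn{Var(Y \mid G = g) = (\beta_2 + \beta_3 g)^2 Var(C) +
#' \sigma^2}, the exact conditional variance of the interaction model when
#' the covariate is independent of the genotype. The result does not depend
#' on \eqn{\beta_0} or \eqn{\beta_1}.
#'
#' @param model A [trait_model()].
#' @param g Centered genotype value(s); defaults to the three genotype
#'   classes \eqn{-2p, 1-2p, 2-2p}.
#' @return Numeric vector of conditional variances (trait units squared),
#'   named by allele count when `g` is the default.
#' @export
variance_by_genotype <- function(model, g = NULL) {
  stopifnot(inherits(model, "trait_model"))
  named <- is.null(g)
  if (named) g <- c(0, 1, 2) - 2 * model$maf
  v <- (model$beta2 + model$beta3 * g)^2 * covariate_variance(model) +
    model$noise_sd^2
  if (named) names(v) <- c("0", "1", "2")
  v
}

#' Partition total trait variance into model components
#'
#' Under independence of \eqn{G} and \eqn{C} all covariance terms vanish and
#' the total variance decomposes as
#' \deqn{Var(Y) = \beta_1^2\, 2p(1-p) + \beta_2^2\, Var(C) +
#'       \beta_3^2\, 2p(1-p)\, Var(C) + \sigma^2.}
#' The fractions of total variance attributable to the covariate and to the
#' interaction are the effect-size scales on which power is reported.
#'
#' @param model A [trait_model()].
#' @return An object of class `"variance_partition"`: list with
#'   `total_variance`, `components` and `fractions` (named
#'   `marginal_g`, `covariate`, `interaction`, `noise`; fractions sum to 1).
#' @export
variance_partition <- function(model) {
  stopifnot(inherits(model, "trait_model"))
  var_g <- genotype_variance(model$maf)
  var_c <- covariate_variance(model)
  comp <- c(marginal_g  = model$beta1^2 * var_g,
            covariate   = model$beta2^2 * var_c,
            interaction = model$beta3^2 * var_g * var_c,
            noise       = model$noise_sd^2)
  total <- sum(comp)
  structure(list(total_variance = total, components = comp,
                 fractions = comp / total),
            class = "variance_partition")
}

#' @export
#' @method print variance_partition
print.variance_partition <- function(x, ...) {
  cat(sprintf("Total trait variance: %.6g\n", x$total_variance))
  f <- x$fractions
  cat(sprintf("  marginal G: %6.3f%%   covariate: %6.3f%%   interaction: %6.3f%%   noise: %6.3f%%\n",
              100 * f[["marginal_g"]], 100 * f[["covariate"]],
              100 * f[["interaction"]], 100 * f[["noise"]]))
  invisible(x)
}

#' Calibrate the interaction coefficient from a target variance fraction
#'
#' Inverts the interaction share of the variance partition: given the target
#' fraction \eqn{f} of total variance to be explained by the product term,
#' solves
#' \deqn{\beta_3^2 = \frac{f\,(\beta_1^2\, 2p(1-p) + \beta_2^2 Var(C) +
#'       \sigma^2)}{2p(1-p)\, Var(C)\,(1-f)}}
#' and returns the non-negative root (power is invariant to the sign of
#' \eqn{\beta_3} under symmetric noise).
#'
#' @param target_frac Target interaction fraction in [0, 1).
#' @param maf Allele frequency of the focal SNP.
#' @param beta1,beta2 Marginal effects of genotype and covariate.
#' @param var_c Variance of the covariate (1 for a standardized covariate,
#'   \eqn{2q(1-q)} for a partner SNP).
#' @param noise_sd Residual standard deviation.
#' @return The non-negative `beta3` reproducing `target_frac`.
#' @export
beta3_for_fraction <- function(target_frac, maf, beta1 = 0, beta2 = 0,
                               var_c = 1, noise_sd = 1) {
  if (!is.numeric(target_frac) || length(target_frac) != 1L ||
      target_frac < 0 || target_frac >= 1)
    stop("'target_frac' must be in [0, 1)", call. = FALSE)
  if (target_frac == 0) return(0)
  var_g <- genotype_variance(maf)
  rest <- beta1^2 * var_g + beta2^2 * var_c + noise_sd^2
  sqrt(target_frac * rest / (var_g * var_c * (1 - target_frac)))
}

#' Write and read a flat model configuration
#'
#' Serializes a [trait_model()] to a plain `key = value` text file (one key
#' per field) so that simulation and power runs are reproducible from the
#' command line, and reads such a file back.
#'
#' @param model A `trait_model`.
#' @param path File path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `trait_model`.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "trait_model"))
  fields <- c("maf", "maf2", "beta0", "beta1", "beta2", "beta3",
              "covariate", "noise_sd")
  lines <- vapply(fields, function(f) {
    v <- model[[f]]
    if (is.null(v)) return(NA_character_)
    sprintf("%s = %s", f,
            if (is.character(v)) v else format(v, digits = 17))
  }, character(1))
  writeLines(lines[!is.na(lines)], path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  named <- stats::setNames(as.list(vals), keys)
  num <- function(k, default = NULL)
    if (k %in% keys) as.numeric(named[[k]]) else default
  trait_model(maf = num("maf"),
              beta0 = num("beta0", 0), beta1 = num("beta1", 0),
              beta2 = num("beta2", 0), beta3 = num("beta3", 0),
              covariate = if ("covariate" %in% keys) named[["covariate"]]
                          else "normal",
              maf2 = num("maf2"), noise_sd = num("noise_sd", 1))
}
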