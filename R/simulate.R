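#' Simulate one replicate of the interaction model
#'
#' Draws `n` individuals from a [trait_model()]: allele counts of the focal
#' SNP are i.i.d. Binomial(2, p) (Hardy-Weinberg equilibrium) and centered
#' by the true model frequency; the covariate is an independent standard
#' normal (`simulate_gxe`) or a second, independently drawn, centered SNP
#' (`simulate_gxg`); the trait is
#' \eqn{y = \beta_0 + \beta_1 g + \beta_2 c + \beta_3 g c + \epsilon} with
#' \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' Monomorphic genotype draws (possible at low MAF and small `n`) are kept;
#' downstream Levene tests flag them as degenerate, mirroring what an
#' analyst running the screen would observe.
#'
#' @param model A `trait_model` (covariate kind must match the function).
#' @param n Number of individuals (>= 2).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the global RNG state is left untouched.
#' @return An object of class `"sim_dataset"`: list with `y`, `g1`
#'   (centered genotype), `counts1` (raw allele counts), `covariate`
#'   (and, for the gene-by-gene design, `counts2`), `model`, `n`, `seed`.
#' @examples
#' d <- simulate_gxe(trait_model(maf = 0.2, beta2 = 0.3), n = 100, seed = 1)
#' var(d$y)
#' @export
simulate_gxe <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "trait_model"))
  if (model$covariate != "normal")
    stop("simulate_gxe() needs covariate = \"normal\"", call. = FALSE)
  check_n(n)
  with_seed(seed, {
    counts1 <- stats::rbinom(n, 2L, model$maf)
    covar <- stats::rnorm(n)
    build_sim(model, n, seed, counts1, covar, counts2 = NULL)
  })
}

#' @rdname simulate_gxe
#' @export
simulate_gxg <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "trait_model"))
  if (model$covariate != "snp")
    stop("simulate_gxg() needs covariate = \"snp\"", call. = FALSE)
  check_n(n)
  with_seed(seed, {
    counts1 <- stats::rbinom(n, 2L, model$maf)
    counts2 <- stats::rbinom(n, 2L, model$maf2)
    covar <- as.numeric(counts2) - 2 * model$maf2
    build_sim(model, n, seed, counts1, covar, counts2)
  })
}

build_sim <- function(model, n, seed, counts1, covar, counts2) {
  g1 <- as.numeric(counts1) - 2 * model$maf
  y <- model$beta0 + model$beta1 * g1 + model$beta2 * covar +
    model$beta3 * g1 * covar + stats::rnorm(n, 0, model$noise_sd)
  structure(list(y = y, g1 = g1, counts1 = counts1, covariate = covar,
                 counts2 = counts2, model = model, n = n, seed = seed),
            class = "sim_dataset")
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2", call. = FALSE)
}

## Evaluate expr with a temporary RNG state when seed is given; the caller's
## .Random.seed is restored afterwards (same convention as simulate()).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive per-replicate seeds from a root seed (kept below 2^31).
spawn_seeds <- function(seed, reps) {
  if (is.null(seed)) return(rep(list(NULL), reps))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, reps)))
}

#' @export
#' @method print sim_dataset
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated interaction dataset: n = %d, design = %s\n",
              x$n, if (x$model$covariate == "normal") "GxE" else "GxG"))
  cat(sprintf("  trait mean %.4g, variance %.4g; MAF (realized) %.4g\n",
              mean(x$y), stats::var(x$y), mean(x$counts1) / 2))
  invisible(x)
}

#' Simulate method for trait models
#'
#' Draws `nsim` independent replicate datasets from the model, dispatching
#' on the covariate kind to [simulate_gxe()] or [simulate_gxg()]. Each
#' replicate gets its own seed spawned from `seed`, so runs are reproducible
#' and replicates independent.
#'
#' @param object A [trait_model()].
#' @param nsim Number of replicates.
#' @param seed Optional integer root seed.
#' @param n Individuals per replicate.
#' @param ... Unused.
#' @return A list of `nsim` `"sim_dataset"` objects.
#' @export
simulate.trait_model <- function(object, nsim = 1, seed = NULL, n, ...) {
  seeds <- spawn_seeds(seed, nsim)
  fun <- if (object$covariate == "normal") simulate_gxe else simulate_gxg
  lapply(seeds, function(s) fun(object, n = n, seed = s))
}

#' Generate a null genotype panel with planted QC failures
#'
#' Builds a genotype matrix (individuals x SNPs, allele counts 0/1/2 with
#' `NA` for missing calls) whose clean SNPs are drawn under Hardy-Weinberg
#' equilibrium at frequencies uniform over `maf_range`, with labelled
#' subsets planted to violate quality-control thresholds so that filters
#' can be tested against ground truth:
#' \itemize{
#'   \item `n_low_call` SNPs receive call rate `low_call_rate` (below the
#'     usual 90\% threshold by default);
#'   \item `n_hwe_violators` SNPs are drawn all-heterozygote, an extreme
#'     excess of heterozygosity that the exact test flags at any realistic
#'     sample size;
#'   \item `n_low_maf` SNPs are drawn at allele frequency `low_maf`
#'     (below the usual 1\% threshold by default).
#' }
#' All SNPs are trait-independent, so a Levene scan over the panel is a
#' global null.
#'
#' @param n_snps Total number of SNPs.
#' @param n_individuals Number of individuals.
#' @param maf_range Length-2 range of clean-SNP allele frequencies.
#' @param missing_rate Baseline per-call missingness for clean SNPs.
#' @param n_low_call,low_call_rate Count and call rate of planted
#'   low-call-rate SNPs.
#' @param n_hwe_violators Count of planted all-heterozygote SNPs.
#' @param n_low_maf,low_maf Count and frequency of planted rare SNPs.
#' @param seed Optional integer seed.
#' @return A list with `genotypes` (matrix, rownames sample ids, colnames
#'   SNP ids), `maf` (true frequencies), `label` (per-SNP ground truth:
#'   "clean", "low_call", "hwe_violation" or "low_maf"), and `seed`.
#' @export
simulate_null_panel <- function(n_snps, n_individuals,
                                maf_range = c(0.05, 0.5),
                                missing_rate = 0,
                                n_low_call = 0, low_call_rate = 0.85,
                                n_hwe_violators = 0,
                                n_low_maf = 0, low_maf = 0.005,
                                seed = NULL) {
  stopifnot(n_snps >= 1, n_individuals >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            n_low_call + n_hwe_violators + n_low_maf <= n_snps)
  with_seed(seed, {
    n_clean <- n_snps - n_low_call - n_hwe_violators - n_low_maf
    label <- rep(c("clean", "low_call", "hwe_violation", "low_maf"),
                 c(n_clean, n_low_call, n_hwe_violators, n_low_maf))
    label <- sample(label)
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    maf[label == "low_maf"] <- low_maf
    G <- matrix(NA_integer_, n_individuals, n_snps,
                dimnames = list(paste0("ind", seq_len(n_individuals)),
                                paste0("snp", seq_len(n_snps))))
    for (j in seq_len(n_snps)) {
      g <- if (label[j] == "hwe_violation") rep(1L, n_individuals)
           else stats::rbinom(n_individuals, 2L, maf[j])
      ## planted low-call SNPs get a fixed missing count so their call rate
      ## is below threshold by construction, not just in expectation
      n_miss <- if (label[j] == "low_call")
        ceiling(n_individuals * (1 - low_call_rate))
      else if (missing_rate > 0) stats::rbinom(1L, n_individuals, missing_rate)
      else 0L
      if (n_miss > 0) g[sample.int(n_individuals, n_miss)] <- NA_integer_
      G[, j] <- g
    }
    list(genotypes = G, maf = maf, label = label, seed = seed)
  })
}

#' Write and read tabular genotype and phenotype fixtures
#'
#' `write_dosage_tsv()` writes an additive-dosage matrix (individuals as
#' rows, one SNP per column, missing coded `NA`) with the sample id in the
#' first column; `read_dosage_tsv()` reads it back. `write_phenotype_tsv()`
#' and `read_phenotype_tsv()` handle two-column `(id, value)` tables for
#' traits and covariates.
#'
#' @param genotypes Integer matrix of allele counts (0/1/2/NA), rownames =
#'   sample ids, colnames = SNP ids.
#' @param path Output file.
#' @return Readers return the matrix (or named numeric vector); writers
#'   return `path` invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' @rdname write_dosage_tsv
#' @param values Named numeric vector (names = sample ids), or a numeric
#'   vector plus `ids`.
#' @param ids Sample ids (defaults to `names(values)`).
#' @param name Column name for the value column.
#' @export
write_phenotype_tsv <- function(values, path, ids = names(values),
                                name = "value") {
  if (is.null(ids)) stop("sample ids are required", call. = FALSE)
  df <- data.frame(id = ids, v = as.numeric(values))
  names(df)[2] <- name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric"))
  stats::setNames(df[[2]], df[[1]])
}

#' Write a minimal VCF with GT genotypes
#'
#' Emits an uncompressed VCFv4.2 file carrying only the GT FORMAT field,
#' with one biallelic record per SNP (`0/0`, `0/1`, `1/1`, `./.`), suitable
#' as a text fixture for the scan pipeline. Read back with
#' [read_vcf_dosage()].
#'
#' @param genotypes Allele-count matrix as in [write_dosage_tsv()].
#' @param path Output `.vcf` path.
#' @param chrom,pos Optional per-SNP chromosome and position (defaults:
#'   chromosome "1", positions 1000, 2000, ...).
#' @return `path`, invisibly.
#' @export
write_vcf_gt <- function(genotypes, path, chrom = NULL, pos = NULL) {
  n_snp <- ncol(genotypes)
  if (is.null(chrom)) chrom <- rep("1", n_snp)
  if (is.null(pos)) pos <- 1000L * seq_len(n_snp)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)),
                    collapse = "\t"))
  body <- vapply(seq_len(n_snp), function(j) {
    g <- genotypes[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(chrom[j], pos[j], colnames(genotypes)[j], "A", "G", ".",
            "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Parses a VCF with vcfR and converts GT calls into an additive-dosage
#' matrix (individuals x SNPs, allele counts 0/1/2, `NA` for missing).
#' Multi-allelic records are skipped with a warning; phased separators are
#' accepted.
#'
#' @param path VCF file path.
#' @return Integer matrix of allele counts, rownames = sample ids,
#'   colnames = SNP ids (falling back to `chrom:pos` when ID is missing).
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  })
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  out <- t(counts)
  colnames(out) <- ids
  storage.mode(out) <- "integer"
  out
}
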