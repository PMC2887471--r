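---
title: "Variance prioritization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance prioritization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprio)
```

## The model and why variance screening works

`varprio` targets interactions on quantitative traits. The generative model
for individual $i$ is

$$Y_i = \beta_0 + \beta_1 G_i + \beta_2 C_i + \beta_3 G_i C_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $G$ is a biallelic SNP in Hardy–Weinberg equilibrium at minor allele
frequency $p$, additively coded and centered ($-2p$, $1-2p$, $2-2p$, so the
population mean genotype is zero and its variance is $2p(1-p)$), and $C$ is
an interacting covariate independent of $G$: either a standardized
environmental exposure (mean 0, variance 1) or a second, independent,
centered SNP with variance $2q(1-q)$.

Conditioning on the genotype class $g$ collapses the model to a location
shift plus a scaled covariate, so

$$\mathrm{Var}(Y \mid G = g) = (\beta_2 + \beta_3 g)^2\,\mathrm{Var}(C) + \sigma^2 .$$

Two facts drive everything in the package. First, the conditional variance
differs across genotype classes **exactly when $\beta_3 \neq 0$**, so
variance heterogeneity is a signature of interaction. Second, it does not
involve $\beta_1$: a SNP with no marginal effect whatsoever still betrays
its interactions through its variance pattern, and — because $C$ enters only
through $\mathrm{Var}(C)$ — the interacting partner need not be measured or
even known for the SNP to be flagged.

With $G \perp C$, the total variance decomposes additively,

$$\mathrm{Var}(Y) = \beta_1^2\, 2p(1-p) + \beta_2^2\, \mathrm{Var}(C)
  + \beta_3^2\, 2p(1-p)\, \mathrm{Var}(C) + \sigma^2,$$

and `variance_partition()` reports each term as a fraction of the total.
Effect sizes throughout the package are expressed on the scale of the
**interaction fraction** — the share of total variance attributable to the
product term — because that is the scale on which power is comparable
across allele frequencies and covariate effects. `beta3_for_fraction()`
inverts the partition,

$$\beta_3^2 = \frac{f\,(\beta_1^2\, 2p(1-p) + \beta_2^2 \mathrm{Var}(C) + \sigma^2)}
  {2p(1-p)\,\mathrm{Var}(C)\,(1-f)},$$

returning the non-negative root; power is invariant to the sign of
$\beta_3$ under symmetric noise, so nothing is lost.

## Levene's test as the screening statistic

The screen is the $k$-group Levene test with **group-mean centering**:
$Z_{ij} = |y_{ij} - \bar y_i|$ and

$$W = \frac{N-k}{k-1}\cdot
  \frac{\sum_i N_i (\bar Z_i - \bar Z)^2}{\sum_i \sum_j (Z_{ij} - \bar Z_i)^2}
  \;\sim\; F_{k-1,\,N-k} \text{ under } H_0 .$$

The mean-centered form (not the median-centered Brown–Forsythe variant) is
used deliberately: it is the classical statistic, and its robustness to
non-normality — unlike Bartlett's test, which inflates type-I error badly
on real traits — is what makes a genome-wide variance scan feasible.
Implementation choices:

* genotype classes absent from the sample reduce $k$ (a SNP with no
  minor-allele homozygotes is tested with $k = 2$); singleton groups are
  retained and simply contribute nothing to the denominator;
* individuals missing either trait or genotype are dropped pairwise — the
  simplest deterministic rule;
* a monomorphic SNP, or data whose absolute deviations are constant within
  every group, yields a **degenerate** result (`NA` statistic, flagged)
  rather than an error, because both occur routinely in scans and must
  propagate as non-rejections;
* p-values come from the upper tail of the F distribution, with no
  continuity correction.

## The two-step procedure and its multiple-testing accounting

`prioritize_and_test()` screens every SNP at level $\alpha_L$ and then
tests only prioritized SNPs by OLS of $Y$ on $(1, G, C, G\!\cdot\!C)$, the
two-sided $t$-test on the product coefficient with $n-4$ df. The
second-step threshold from `corrected_threshold()` is

* G×E: $\mathrm{FWER} / (\alpha_L \cdot M \cdot \#\text{covariates})$,
* G×G: $\mathrm{FWER} / (\alpha_L \cdot M^2)$,

with $M$ the panel size (default 340,000, the scale of a post-QC GWAS
array). The logic: under the global null a fraction $\alpha_L$ of the panel
passes the screen, so $\alpha_L M$ is the expected number of second-step
tests. Setting $\alpha_L = 1$ makes the screen vacuous and recovers the
exhaustive Bonferroni thresholds ($0.05/340{,}000 \approx 1.5\times10^{-7}$;
$0.05/340{,}000^2 \approx 4.3\times10^{-13}$).

Three accounting choices were genuinely open and are resolved as follows.
The G×G denominator uses $\alpha_L M^2$ (ordered pairs) rather than
$\alpha_L M (M-1)/2$, because prioritized SNPs are tested against **all**
panel SNPs — restricting partners to prioritized SNPs is markedly less
powerful — and because the exhaustive all-pairs threshold then collapses
correctly to $0.05/M^2$. A pair in which *both* members pass the screen is
one hypothesis and is tested once (deduplicated on the unordered pair).
With several declared environmental covariates, each prioritized SNP is
tested against each, so the declared covariate count enters the denominator
multiplicatively; the default of 1 reproduces the single-covariate
accounting, and small follow-up sets are naturally handled by
`panel_size = #SNPs`, `n_covariates = #traits`.

## What the simulator emulates — and what it does not

`simulate_gxe()` / `simulate_gxg()` draw allele counts i.i.d.
$\mathrm{Binomial}(2, p)$ — random HWE sampling, not fixed expected counts —
center them by the **true** model frequency (analysis functions center by
the sample frequency instead, since only that exists for real data), draw
$C$ independently, and add unit-variance Gaussian noise by default, so the
trait is standardized conditional on $(G, C)$. The study conditions baked
into the power defaults are those of the simulation experiments the package
reproduces: $n = 15{,}000$ individuals per replicate, 1,000 replicates for
single-condition power (2,000 for prioritization-versus-exhaustive
comparisons), interaction fractions up to 1% — interactions in real data
are expected to be modest at best — and equal allele frequencies and main
effects for the two SNPs of the G×G design.

The generator deliberately omits linkage disequilibrium between SNPs,
population structure, ascertainment, non-Gaussian noise and non-additive
(dominance/recessive) codings. Passing tests therefore demonstrate
correctness of the statistics under the stated model, not robustness of the
screen on real cohorts, where variance heterogeneity can also arise from
scale effects (variance proportional to the mean — consider a log or
square-root transform first), LD with a large-effect variant, or multiple
overlapping interactions.

`simulate_null_panel()` builds genome-scan fixtures: trait-independent HWE
SNPs plus labelled subsets planted to violate each QC rule (low call rate,
all-heterozygote HWE violations, sub-threshold MAF), giving the filters a
ground truth. Planted low-call SNPs receive a *fixed* missing count so they
sit below the call-rate threshold by construction rather than in
expectation.

## Monte-Carlo power machinery

`power_replicates()` simulates one causal SNP (plus partner) per replicate
and caches the Levene p-value(s) and the interaction p-value; all power
summaries — screen power, exhaustive-regression power, and the
variance-prioritization curve over an $\alpha_L$ grid (default: 20
log-spaced points in $[10^{-7}, 1]$) — are then evaluated on **common
random numbers**, so comparisons between procedures are not diluted by
independent simulation noise, and `alpha_levene = 1` reproduces the
exhaustive search *exactly*, replicate by replicate. The surrounding SNP
panel enters only through the correction denominators, which is what makes
genome-scale power experiments runnable in seconds. Every estimate carries
its binomial standard error $\sqrt{\hat\pi(1-\hat\pi)/R}$; replicates with
monomorphic draws count as non-rejections, matching what an analyst would
observe. A root seed spawns independent per-replicate seeds, so runs are
reproducible and single replicates can be re-examined.

`analytic_power_oracle()` provides an independent cross-check: treating the
regressors' moments as fixed at their population values, the interaction
$F$-statistic is approximately noncentral $F(1, n-4)$ with noncentrality
$n f^2$, where $f^2$ is the ratio of interaction-explained to residual
variance from the partition. It is an approximation (it ignores design
randomness) and is used to validate the Monte-Carlo engine within
simulation error, never to replace it.

## The independence property and its boundary

The validity of the two-step correction rests on the interaction test
being independent of the screen under the null of no interaction, so that
screening does not distort the null distribution of second-step p-values.
`independence_diagnostic()` checks this empirically: simulate null
replicates ($\beta_3 = 0$), keep those passing the screen, and examine the
selected interaction p-values against Uniform(0,1) (QQ data with pointwise
beta-order-statistic bands and a Kolmogorov–Smirnov p-value).

Working through this package's test suite surfaced a genuine boundary of
that property. When the covariate has **no marginal effect**
($\beta_2 = 0$), selected interaction p-values are uniform to Monte-Carlo
precision, as theory predicts for Gaussian traits: the interaction
estimate, a linear form in the noise, is uncorrelated with the
genotype-class *sample variances* (quadratic forms), whose Gaussian
cross-moments with linear forms vanish. But Levene's statistic is built
from absolute deviations, not variances, and when $\beta_2 \neq 0$ the
cross-moment $E[C\,u\,|u|]$ (with $u = \beta_2 C + \varepsilon$) is
non-zero, coupling the screen to the interaction estimate. Empirically
(confirmed with an independent `car::leveneTest` + `lm` route), selecting
null replicates at Levene $p < 0.05$ with $\beta_2 = 0.3$ inflates the
conditional rejection rate at nominal 0.05 to roughly 0.08–0.10, and the
effect does not vanish with sample size. The practical implication is mild
— the two-step family-wise error can exceed its budget by a small factor
when screened traits carry strong covariate main effects — but users
pushing the procedure to extreme significance thresholds should know the
screen is only *approximately* independent of the confirmatory test in
that regime. The test suite asserts exact conditional uniformity where the
theory guarantees it ($\beta_2 = 0$) and separately asserts the existence
of the small $\beta_2 \neq 0$ inflation, so the boundary is pinned down
rather than averaged away.

## Quality control and the genome scan

`qc_filter()` applies the standard sequence in a fixed order: samples with
missingness above 2% are removed first; among retained samples, SNPs with
call rate below 90% are dropped, then SNPs with exact Hardy–Weinberg
p-value below $10^{-6}$, then SNPs with MAF $\le$ 1% (strict bound: MAF
must exceed the floor). Computing HWE after sample removal matters — the
exclusions are not interchangeable — and the filter is idempotent. The HWE
test is the exact conditional test on the heterozygote count given the
allele counts, using the plain (not mid-) p-value; the test suite verifies
it against full enumeration for every genotype table up to $n = 200$.

`genome_scan_levene()` reports, per SNP, the sample MAF, per-genotype
counts and variances, $W$, the Levene p-value, and a genome-wide
significance flag, plus QQ data whose pointwise 95% bands come from the
Beta$(i, m-i+1)$ law of uniform order statistics. Trait transformation is
the caller's responsibility (the CLI offers `--log-trait` for right-skewed
biomarkers). `levene_adjusted()` supports the follow-up question "how much
of this SNP's variance signal does a *named* interaction explain?": it
refits the interaction model, re-screens the residuals, and leaves any
residual heterogeneity — e.g. from further unmeasured partners — intact.

## Numerical choices and problem sizes

Tolerances: $\beta_3$ calibration round-trips to $10^{-10}$; Levene and
OLS results match independent oracles to at least 10–12 significant
digits; Monte-Carlo comparisons are asserted within three binomial (or
variance-of-variance) standard errors. Rank deficiency in the OLS design
is detected through the Cholesky factor of $X^\top X$ with a relative
pivot floor of $\sqrt{\epsilon_{\text{machine}}}$ and yields a flagged
degenerate result. The test suite runs the two headline power conditions
at full scale (1,000 × and 2,000 × $n = 15{,}000$), the independence
diagnostic at 12,000 replicates of $n = 1{,}000$, and large-sample moment
checks at $n = 10^6$; the whole suite completes in a couple of minutes on
one CPU.

## Known limitations

* The screen's independence from the confirmatory test is exact only when
  the interacting covariate has no marginal effect (see above).
* Only the additive genotype coding is implemented; dominance or recessive
  interactions may produce little or no variance heterogeneity.
* One covariate at a time: no joint multi-SNP or multi-covariate
  interaction models, no FDR control (Bonferroni only), no permutation
  FWER.
* The scan does not impute, prune LD, or adjust for ancestry; binary
  traits are out of scope.
* A SNP with many partners of opposing effects, or a mis-scaled trait, can
  defeat or mimic the variance signature; the screen prioritizes, it does
  not confirm.
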