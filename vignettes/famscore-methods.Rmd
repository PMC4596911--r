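---
title: "Score tests for multiplex-family case-control association: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score tests for multiplex-family case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscore)
```

## The model

`famscore` tests association between a diallelic marker and a binary (or
quantitative) phenotype when cases are drawn from families ascertained
through multiple affected members. Because ascertainment conditions on
phenotype, the natural likelihood is retrospective — genotype given
phenotype — and the score statistic under it is the genotype–phenotype
covariance

$$U = (Y - \bar Y)^\top X, \qquad
  \operatorname{Var} U = (Y - \bar Y)^\top [K \circ \Sigma](Y - \bar Y),$$

with $U^2/\operatorname{Var}U \sim \chi^2_1$ under the null. $X$ is the
dosage under a genetic-model coding, $\Sigma_{ij} = \sigma_i\sigma_j$ uses
genotypic variances estimated from genotype *frequencies* (so
Hardy–Weinberg proportions are not assumed by the variance), and $K$ holds
pairwise genotype correlations derived from the pedigree. For unrelated
samples $K = I$ and the additive statistic coincides with the
Cochran–Armitage trend test; the test suite asserts both facts against an
independent implementation.

Key modelling assumptions: founders are non-inbred and mutually unrelated
(inbred pedigrees are rejected with an explicit error rather than guessed
at); families are outbred so $K$ is block diagonal by family; the phenotype
enters only through the weights, so no effect-size model is fitted.

## Genotype correlations from pedigrees

The pair correlation is $\rho_{ij} = \pi_2 + \pi_1 \rho_T$, where
$(\pi_0,\pi_1,\pi_2)$ are IBD-sharing probabilities and $\rho_T$ is the
conditional correlation given one shared allele: $1/2$ for the additive
coding and $\hat p/(1+\hat p)$ for the recessive coding at risk-allele
frequency $\hat p$ (so recessive correlations are frequency-dependent:
a sib pair has $\rho = (1+3\hat p)/(4(1+\hat p))$). The dominant coding is
the recessive coding after flipping allele labels, and is implemented that
way throughout — coding, variance and correlation — which makes the
dominant/recessive label-swap identity exact by construction (still
asserted in the tests, since it exercises the full path).

$\pi_2$ needs more than ordinary kinship. We compute it by generalized
kinship recursions (two-pair coefficients in the style of Karigl), after
internally giving every founder a pair of virtual unrelated founder
parents. The extension changes no identity coefficient of real individuals
but lets a single pair formula
$\pi_2 = \phi_{22}(f_i,f_j;m_i,m_j) + \phi_{22}(f_i,m_j;m_i,f_j)$ cover
founder and parent–offspring pairs uniformly. The recursions are memoized
per pedigree and validated three ways: printed textbook values (sibs,
double first cousins), an exact transmission-enumeration oracle
($10^{-12}$), and a 200,000-replicate gene-dropping simulation (3
Monte-Carlo SEs, with the SE estimated by block resampling because the
bivariate-normal formula understates it for discrete dosages).

### X-linked markers

Males are treated as homozygous females (X-inactivation argument): male
hard calls are coded 0/2, so dosage expectations match between sexes while
the male genotypic variance is twice the female one under HWE. The package
does not enforce that factor of two: $\Sigma$ uses sex-specific standard
deviations estimated from the observed counts (female genotype
frequencies; male allele frequency), preserving robustness to departures
from Hardy–Weinberg proportions. X correlations are
$\rho_X = 2\,\phi_X\, c_i c_j$ with $c_{\text{female}} = 1$,
$c_{\text{male}} = 1/\sqrt 2$ and $\phi_X$ the X-chromosomal kinship (a
male's X is a copy of his mother's); this one formula reproduces all the
classical pair values (sisters 3/4, brothers 1/2, mother–son $1/\sqrt2$,
father–son 0, maternal uncle–niece $1/(4\sqrt2)$) and is checked exactly
against an enumeration oracle over a three-generation pedigree. Recessive
and dominant codings on X are rejected: no defensible correlation model
for them is implemented.

## Imputed genotypes and $R^2_T$

For imputed markers with posterior probabilities
$\varpi = (\varpi_0,\varpi_1,\varpi_2)$ the dosage
$\tilde X = \varpi_1 + 2\varpi_2$ replaces $X$, and the variance is
penalized by the information lost to imputation uncertainty:
$\Sigma_{\text{loss}}$ has diagonal $l_i$ — the posterior variance of the
dosage, zero exactly for hard calls — and off-diagonal $\sqrt{l_i l_j}$
(rank one, PSD), giving

$$\operatorname{Var}_{\text{obs}} U =
  (Y-\bar Y)^\top [K \circ (\Sigma - \Sigma_{\text{loss}})](Y - \bar Y),
 \qquad R^2_T = \frac{\operatorname{Var}_{\text{obs}} U}{\operatorname{Var} U}.$$

$R^2_T \in [0,1]$ is marker- and phenotype-specific (a post-analysis
measure, unlike pre-analysis imputation-quality scores, which the readers
accept only as pass-through metadata) and can be used as a filter
(`min_r2t`). Since $K$ and $\Sigma_{\text{loss}}$ are both PSD, the
penalized variance never exceeds the unpenalized one; if it is
non-positive the marker is reported degenerate rather than tested.
Posterior triples are renormalized when their sum is within 0.01 of 1 and
rejected otherwise (imputation outputs are rounded text). X-linked male
posteriors are collapsed to the two-state $\{0,2\}$ support before the loss
is computed. With dosage-only input (VCF `DS` without `GP`) the loss is
unavailable; the test then runs with $\Sigma_{\text{loss}} = 0$ and the
genotypic variance estimated from the empirical dosage variance.

## Family-history weights

Phenotypes of un-genotyped relatives enter as
$Y^* = Y_n + K_{n,m} Y_m$: each genotyped case gains $\rho_{ij}$ per
affected un-genotyped relative $j$ (affected = 1, unaffected or
missing = 0; the latter is deliberate — no prevalence offset is applied).
$K_{n,m}$ uses the same genetic model as the test's $K$ for internal
consistency. Weights are recomputed per marker because missingness defines
who is "genotyped" at that marker. By default only cases receive
augmentation, mirroring designs that collect family history on cases;
`history_for = "all"` extends it to genotyped controls. $\bar Y^*$ is the
mean of $Y^*$ over the genotyped sample, the same convention as $\bar Y$.
When every family has an identical configuration the centered weights are
an affine transformation of the centered phenotypes and the weighted and
unweighted chi-squares coincide — a property the tests assert — so the
weights only help in mixed designs.

## The ascertained-family simulator

`simulate_dataset()` emulates the study design the tests are meant for:
nuclear families with two HWE founder parents and three offspring by
Mendelian transmission; per-sib disease from
$\operatorname{logit}(\mu) = \beta_0 + \beta_g x + u$ with baseline risk
$K_b = 0.10$ ($\beta_0 = \operatorname{logit} K_b$), odds ratio
$e^{\beta_g}$ on the model-appropriate genotypic score, and a shared
family effect $u \sim N(0, \sigma_u^2)$ for residual familial correlation.
With the intrinsic logistic residual taken as $\approx 3$ on the liability
scale, $\sigma_u^2 = 1$ labels a broad-sense heritability of roughly 25%
and $\sigma_u^2 = 0.5$ roughly 14%; the labels are bookkeeping, not an
extra noise term. Families are rejection-sampled to the exact affection
pattern of the scheme (ASP1/ASP2/ASP3 = exactly one/two/three affected
sibs; Mixed = equal thirds), one affected sib is genotyped as the case
(uniformly chosen — the design states only that one individual is
selected), the remaining sibs stay as un-genotyped relatives with their
phenotypes, and controls are unrelated singletons with no phenotype
screening. On X, the father carries one Bernoulli X allele plus a Y, and
whether he transmits X or Y sets the offspring sex; male scores use the
0/2 coding. Null simulations default to $\sigma_u^2 = 1$ (type-I error is
insensitive to it; it remains a parameter).

What the simulator does *not* emulate: linkage disequilibrium and
haplotype structure, genotyping error, population stratification,
realistic imputation posteriors (test posteriors are made by blurring true
genotypes), variable sibship sizes, or phenotyped parents. Passing
simulation-based tests therefore says nothing about robustness to
stratification or LD — only about calibration and power under the stated
ascertainment model.

`empirical_rate()` runs the full pipeline per replicate. Because each case
family contributes exactly one genotyped individual, the genotyped sample
is mutually unrelated ($K = I$) and the per-replicate test reduces to a
vectorized kernel whose sib correlations for $Y^*$ are taken from the real
pair-coefficient machinery evaluated once on a template nuclear family; a
test asserts the kernel equals the general pipeline on the same dataset to
$10^{-10}$. Empirical rates use 1000 replicates for null calibration and
400 for power runs — enough for binomial SEs of ~0.007 and ~0.02
respectively, which is the resolution at which the results are read.

## Numerical choices and degenerate inputs

* **No sample-size normalization of the variance.** The quadratic form is
  used as is: scaling it by $n^{-1}$ would break the unrelated-sample
  limit ($K = I$ must recover $\sigma^2\sum_i (y_i-\bar y)^2$) and inflate
  the type-I error roughly $n$-fold. The null-calibration tests pin this
  down empirically.
* **Frequency source.** Pooled cases + controls by default (efficient
  under the null and what makes the Cochran–Armitage equivalence exact);
  controls-only is available (`freq_source = "controls"`) for users who
  prefer a null-consistent estimate under strong enrichment.
* **Degenerate markers.** Monomorphic markers, or markers whose penalized
  variance is non-positive, return `status = "degenerate"` with `p = NA`;
  the power machinery counts them as non-rejections (they matter for rare
  recessive variants, where many replicates carry no informative
  homozygote).
* **MZ twins.** A PLINK `.fam` file cannot encode monozygosity, so both
  twins would enter as ordinary sibs; since the test never inverts $K$,
  a singular $K$ would be harmless anyway.
* **Ties and tie-breaks.** The selected case among several affected sibs
  is uniform random; marker ids falling back to `chrom:pos` when the VCF
  ID is missing.

## Known limitations

Power of *recessive* tests under multi-affected ascertainment is acutely
sensitive to how the disease depends on genotype. With the disease
generated by the recessive indicator score itself — the package's reading,
which keeps the generating and tested models aligned — the case-homozygote
enrichment for an all-affected sibship at homozygote frequency 0.09 and
odds ratio 1.5 is 0.09 → ~0.14, and the resulting power (about 0.73 at 500
families in the acceptance run) is far below what an additively generated
disease would yield under the same recessive test. Users comparing against
external power figures for recessive multiplex designs should check which
generating score was used, since the two readings differ by 20+ points of
power at common allele frequencies. Other limitations: no covariate
adjustment, no effect-size estimation (score test only), no BGEN/PLINK
binary input, and no multiple-testing correction beyond reporting raw
p-values.
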