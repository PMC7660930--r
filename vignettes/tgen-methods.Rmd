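---
title: "Annotation-informed expression imputation and summary-statistics TWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-informed expression imputation and summary-statistics TWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgen)
```

## The problem

Transcriptome-wide association studies (TWAS) test whether the genetically
regulated component of a gene's expression is associated with a trait. The
workflow has two stages. First, per gene and tissue, expression is regressed
on cis-SNP dosages to obtain a sparse weight vector $\hat\beta$; second,
those weights are combined with GWAS summary z-scores to form a gene-level
association statistic, so no individual-level trait data are needed.

Most of the SNPs in a 1 Mb cis window are irrelevant, and the eQTLs that do
regulate expression tend to sit in epigenetically active sequence (marked by
H3K4me1, H3K4me3, H3K9ac, accessible chromatin, low DNA methylation). `tgen`
exploits this: each SNP's prior probability of being an eQTL is a logistic
function of its tissue-specific epigenetic annotation values, learned
jointly with the SNP effects.

## The model

For one gene in one tissue, with $n$ samples, $p$ cis-SNPs and $m$
annotation tracks,

$$Y = X\beta + \epsilon, \qquad \epsilon \sim N(0, \sigma^2 I),$$

with a spike-and-slab prior on each SNP effect:

$$\beta_k \mid \gamma_k = 1 \sim N(0, \sigma_\beta^2 \sigma^2), \qquad
  \beta_k \mid \gamma_k = 0 = 0, \qquad
  \gamma_k \sim \mathrm{Bernoulli}(\pi_k),$$

and the annotation-dependent inclusion prior

$$\mathrm{logit}(\pi_k) = \omega_0 + A_k \omega, \qquad
  \omega \sim N(0, \eta^{-1} I).$$

$X$ is the centered dosage matrix, $Y$ the covariate-adjusted expression
(the package assumes expression is pre-adjusted for platform, ancestry and
expression-residual factors), and $A_k$ the SNP's row of continuous
annotation values — fold enrichments for ChIP/DNase signal, methylation
fractions for DNA methylation. Only entries whose underlying signal is
significant (p < 1e-2 by default) are trusted; the rest are set to zero by
`mask_annotations()`. An explicit intercept $\omega_0$ is always included,
so with no annotation at all the prior reduces to a shared, learned
inclusion probability — that is exactly the `vb` baseline.

The hyperparameters $\theta = (\sigma^2, \sigma_\beta^2, \eta)$ carry
IG$(a,b)$, IG$(c,d)$ and Gamma$(a_0,b_0)$ priors (all 0.01 by default,
weakly informative).

## Variational inference

Exact posterior inference over $2^p$ inclusion patterns is intractable at
cis-window scale, so `fit_single_theta()` uses coordinate-ascent
variational Bayes with the fully factorized family
$q(\beta, \gamma)\,q(\omega) = \prod_k q(\beta_k, \gamma_k)\, q(\omega)$:

* **SNP block.** For SNP $k$ (cyclic, genomic order), the update is the
  standard conjugate spike-and-slab step:
  $s_k^2 = \sigma^2/(x_k^\top x_k + 1/\sigma_\beta^2)$,
  $\mu_k = s_k^2 \, x_k^\top r_{-k} / \sigma^2$ with $r_{-k}$ the residual
  excluding SNP $k$, and
  $\mathrm{logit}(\alpha_k) = A_k^\top m_\omega +
  \tfrac12\log\!\big(s_k^2/(\sigma^2\sigma_\beta^2)\big) + \mu_k^2/(2s_k^2)$.
  The residual is maintained incrementally, so a sweep costs $O(np)$ (the
  sweep is compiled).
* **Annotation block.** The logistic terms are not conjugate; they are
  bounded with the Jaakkola–Jordan quadratic bound with one local parameter
  $\xi_k$ per SNP, which makes $q(\omega)$ Gaussian with closed-form
  precision $\eta I + 2\sum_k \lambda(\xi_k) A_k A_k^\top$ and mean driven
  by $\sum_k (\alpha_k - \tfrac12) A_k$; the $\xi_k$ update is also closed
  form. A bound-based scheme was chosen because it keeps the objective a
  true lower bound that every step increases; sampling or delta-method
  updates would lose that certificate.
* **Residual variance.** $\sigma^2$ is profiled at its closed-form
  ELBO-maximizing value each iteration (`profile_sigma2 = TRUE`), which is
  itself an ascent step, so monotonicity is preserved.

Every update maximizes the same evidence lower bound, so the recorded ELBO
trace is non-decreasing; the test suite enforces this to within 1e-8 per
iteration on randomized instances. Convergence is declared when the ELBO
changes by less than `tol` (1e-4 by default; iteration cap 500).
Initialization: $\alpha_k = 0.1$, $\mu_k = 0$, $\omega = 0$ except the
intercept at $\mathrm{logit}(0.1)$, $\xi_k = 1$.

## Hyperparameter grid and PPS

Rather than updating $\theta$ inside the variational loop, `fit_grid()`
fits at each point of a grid — by default $\sigma_\beta^2 \in \{0.001,
0.01, 0.1, 1\}$ crossed with $\eta \in \{1, 10\}$, $\sigma^2$ profiled —
and weights the fits by $w_\theta \propto \exp\{\mathrm{ELBO}(\theta) +
\log p(\theta)\}$. The posterior probability of selection and the effect
estimate are the weighted averages

$$\mathrm{PPS}_k = \sum_\theta w_\theta\, \alpha_k(\theta), \qquad
  \hat\beta_k = \sum_\theta w_\theta\, \alpha_k(\theta)\, \mu_k(\theta),$$

i.e. $\hat\beta$ is the posterior-mean (selection-shrunk) effect used in
the prediction rule $\hat Y = X\hat\beta$. On small problems ($p \le 8$)
the fitted $\alpha$ agree with exact enumeration over all $2^p$ inclusion
patterns to correlation above 0.99 in our tests.

## Comparators

Four comparison learners share the `fit_model()` surface: `vb` (the same
machinery, intercept-only prior), `elnt` (elastic net with mixing parameter
0.5 and penalty chosen by internal cross-validation, via glmnet), and
`vb.annot`/`elnt.annot`, which first discard SNPs with no positive value on
any chosen annotation track and then fit the base learner.

## Evaluation and the FDR gate

`cross_validate()` refits the chosen method on k−1 folds (k = 5 by
default, folds balanced to within one sample) and pools out-of-fold
predictions; imputation accuracy is the squared Pearson correlation $R^2$
between observed and pooled predicted expression. Model significance is a
one-sided test of positive correlation between observed and out-of-fold
predicted values, computed **within each fold** and combined across folds
by Stouffer's method. The within-fold form matters: conditional on its
training data a fold's predictions are a fixed vector independent of the
held-out responses, so each per-fold p-value is exactly uniform under the
null, whereas a single correlation pooled across folds is negatively
biased (every sample's response also enters the other folds' training
fits). Residual cross-fold dependence makes the combined p-value very
slightly anti-conservative at this design's scale; the null-calibration
test bounds the effect. Folds too small for a correlation (leave-one-out)
fall back to the pooled test.

Genes enter association testing only if their model passes a
Benjamini–Hochberg gate at FDR 0.05 on these p-values, applied per tissue
(`model_fdr_filter()`); BH is the field-standard choice where the
procedure is otherwise unspecified, and a global gate is available by
pooling reports across tissues before calling it.

## The summary-statistics association test

With trait model $T = \mu + \hat Y \kappa_Y + \tau$, the z-score for
$\kappa_Y$ reduces to a weighted sum of per-SNP GWAS z-scores:

$$z \;=\; \hat\beta^\top \Lambda \hat Z_X, \qquad
  \Lambda = \mathrm{diag}\!\left(\frac{\mathrm{sd}(x_k)}
  {\mathrm{sd}(\hat Y)}\right),$$

where the SNP and imputed-expression standard deviations are computed on a
reference genotype panel (empirical SDs, denominator n−1; equivalently
$\mathrm{sd}(\hat Y) = \sqrt{\hat\beta^\top \hat\Sigma_{\mathrm{ref}}
\hat\beta}$). The package validates this identity directly: when the GWAS
cohort itself is used as the reference, the summary statistic agrees with
the z-score from regressing the trait on imputed expression at the
individual level to within 0.1 in essentially all replicates. The
intermediate quantities of the derivation (the standard error of
$\hat\kappa_Y$ and the variance-explained terms) are never computed
separately; only the final identity is implemented and it is checked
against the individual-level oracle.

Before testing, `harmonize()` aligns GWAS allele coding to the model:
matching coding keeps $z$, swapped effect/other alleles flip its sign, and
strand-ambiguous SNPs (A/T, C/G) or mismatched allele pairs are dropped
with recorded reasons (their $\hat\beta$ entries are excluded too).
Significance across a run is declared at the Bonferroni threshold
$\alpha / (\text{number of tested gene–tissue pairs})$; BH is available as
an option. Significant genes can be aggregated into user-supplied
cytogenetic bands; no band map is bundled.

## Synthetic data

`simulate_dataset()` generates linked training, GWAS and reference cohorts
with the statistical structure the model assumes, plus exported ground
truth for recovery tests:

* **Genotypes.** Dosages are Binomial(2, MAF) with MAF uniform on
  [0.05, 0.5]; linkage disequilibrium comes from an AR(1) Gaussian copula
  on the underlying haplotypes (adjacent latent correlation 0.3 by
  default) — the simplest structure that produces the correlated-cis-SNP
  regime the sparse prior has to disentangle.
* **Annotations and effects.** Annotation values are Exp(1) draws
  (non-negative, right-skewed like fold enrichments); inclusion logits are
  $-2 + 2A_k$ by default, so roughly a third of SNPs are causal with
  strong annotation enrichment; causal effects are
  $N(0, \sigma_\beta^2\sigma^2)$ with $\sigma_\beta^2 = 0.01$ against unit
  residual variance, putting realized per-gene heritability around
  0.1–0.3.
* **Trait.** An independent GWAS cohort receives
  $T = \kappa\, X\beta_{\mathrm{true}} + \text{noise}$ scaled to unit
  trait variance ($\kappa = 0.1$ by default); per-SNP z-scores are actual
  marginal-regression t-statistics rather than analytic approximations, so
  the association oracle comparison is meaningful.

What the generator does **not** emulate: realistic recombination and LD
block structure, population stratification, allele-frequency–dependent
architectures, trans effects, non-Gaussian expression noise, and
annotation measurement error. Passing tests therefore certify the
algorithms and their calibration under the assumed model, not performance
on any real cohort.

## Numerical and design choices

* Ambiguous alleles are exactly the complementary pairs A/T and C/G;
  indels are never ambiguous. Missing dosages are mean-imputed per SNP
  before centering.
* SNP–annotation joins take, per track, the maximum value over overlapping
  intervals (and the smallest signal p-value); the rule is configurable in
  spirit but the maximum is the default because overlapping peak calls
  usually describe the same underlying signal at different resolutions.
* Coordinates are 1-based inclusive internally; BED input is converted
  from 0-based half-open at parse time.
* $\omega$ is fitted per gene (the per-gene reading of the model); a
  shared-per-tissue mode is a possible extension but is not built.
* Annotation values are used unstandardized by default (they are already
  on interpretable scales); per-track scaling is available in
  `mask_annotations(standardize = TRUE)`.
* Degenerate cases: all-zero-weight models are rejected as untestable
  ("degenerate model") rather than given z = 0; genes whose SNPs are all
  filtered yield empty flagged models; per-gene failures in a run are
  logged and skipped, never silently dropped.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data:
oracle comparisons at n = 300, p = 8 (20 instances); ELBO monotonicity on
100 randomized instances; annotation benefit and slope recovery on 50
replicates at n = 500, p = 200; association-oracle agreement on 100
replicates with a 2000-sample GWAS cohort doubling as reference; type-I
calibration on 2000 null gene-replicates; cross-validation null
calibration on 200 replicates at n = 100, p = 20. These sizes were chosen
as the smallest at which each property is statistically identifiable.

## Limitations

Imputation $R^2$ for realistic per-gene heritability is modest by nature;
the method's value is in ranking functional SNPs and in the downstream
test, not in high predictive accuracy. The association statistic inherits
the usual TWAS caveats: a significant gene is associated, not causal, and
LD between gene models can spread signal across neighbours. Only cis
windows are modeled; trans regulation is out of scope, as are probit-link
variants of the inclusion prior and multi-tissue joint fitting.
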