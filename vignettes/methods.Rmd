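---
title: "Models and methods in mapgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mapgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models, the tunable parameters and their defaults, what the synthetic
cohorts do and do not emulate, the numerical choices, and the design
decisions taken where the problem left the design open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

A polygenic score estimates inherited disease liability as a weighted sum of
allele dosages, $S_i = \sum_j x_{ij} w_j$. Scores built from a single
large-ancestry GWAS transfer poorly to other ancestries, and traits that are
genetically correlated with the disease carry additional signal that a
single-trait score ignores. The package's pipeline addresses both: it shrinks
each set of ancestry-stratified GWAS effects with an LD-aware Bayesian prior,
then combines the resulting scores in two layers — across ancestries within a
trait, then across traits — with mixing weights learned on a training cohort,
and finally flattens everything back to one variant-level scoring file.

## Spike-and-slab shrinkage

For one GWAS and one LD block with reference correlation matrix $R$, the
model for the standardized marginal effects $\hat\beta$ is
$\hat\beta \sim N(R\beta, R/n)$ with prior
$\beta_j \sim p\,N(0, \sigma^2) + (1-p)\,\delta_0$, $\sigma^2 = h^2/(Mp)$.
The Gibbs sampler updates one variant at a time: with residual
$\tilde\beta_j = \hat\beta_j - \sum_{k\ne j} R_{jk}\beta_k$, the conditional
inclusion odds compare $N(\tilde\beta_j; 0, \sigma^2 + 1/n_j)$ against
$N(\tilde\beta_j; 0, 1/n_j)$, and the slab conditional is
$N\!\big(\tilde\beta_j\,\tfrac{n_j\sigma^2}{n_j\sigma^2+1},\,
\tfrac{\sigma^2}{n_j\sigma^2+1}\big)$. The reported weight is the
Rao–Blackwellised average of (inclusion probability × conditional mean) over
kept iterations — this has far lower Monte-Carlo error than averaging draws
and is exact in the no-LD, $p=1$ limit, which the acceptance suite checks
against the conjugate closed form $\hat\beta_j \frac{h^2/M}{h^2/M + 1/N}$. A
three-variant block is checked against exact enumeration of the $2^3$ causal
configurations. Marginal effects enter as $z_j/\sqrt{n_j}$ and leave as
per-allele weights via $\mathrm{se}_j\sqrt{n_j}$, which makes the
standardization self-inverse regardless of the original scale. For binary
traits the effective sample size $4/(1/\text{cases} + 1/\text{controls})$ is
used when case counts are present.

Defaults: 500 burn-in + 500 kept iterations, one chain, variants updated in
block order. These are desk-scale settings guarded by the oracle tests;
convergence diagnostics across multiple chains are out of scope.

**The hyperparameter grid.** 17 causal fractions
($1.0, 1.8, 3.2, 5.6 \times 10^{-4} \ldots 10^{-1}$, and 1), heritability
scale $s \in \{0.7, 1, 1.4\}$ applied to the LD-score-regression estimate,
and dense versus sparsified LD — 102 candidates per GWAS.

**"Sparse LD" reading.** The third grid axis is implemented as LD-matrix
sparsification: within-block correlations with $|r| < 0.01$ are zeroed and
the matrix is repaired to positive semidefiniteness by eigenvalue clipping
at $10^{-8}$. The alternative reading — zeroing small posterior effects —
is noted and deliberately not implemented.

**Heritability input.** The base $h^2$ comes from LD-score regression on the
observed scale: $E[\chi^2_j] = 1 + N h^2 \ell_j / M$ with block LD scores
$\ell_j = \sum_k r_{jk}^2$, fitted by the canonical two-step weighted
regression (weights $1/(\ell_j (1 + N h^2 \ell_j/M)^2)$). Unweighted OLS is
far too noisy at $M \approx 2000$. Whether the original analysis scaled the
prior on the observed or liability scale is not documented anywhere we can
check; the observed scale is used because the same scale feeds the
$\chi^2$ statistics, and an explicit `h2_hat` override is accepted. The
estimate is clipped to $[10^{-4}, 0.99]$ before use as a prior parameter.

## Scoring and standardization

Allele matching keeps exact matches, resolves swapped and strand-flipped
alleles (swaps contribute via the dosage complement $2 - x$), and drops
strand-ambiguous A/T and C/G variants. Missing dosages are mean-imputed with
$2f$. Raw scores are residualized on the ten ancestry principal components
(OLS with intercept, per ancestry group separately) and z-scaled within each
group. The per-group PC coefficients, mean and SD are persisted with the
model and *reused* on validation cohorts: recomputing them in-sample would
leak validation information into the standardization, and nothing in the
original description forbids the training-constant choice. Because OLS
residualization is linear in the response, the standardized score of a
flattened weight set is an exact affine image of the explicit layer-by-layer
combination — the equivalence the test suite asserts at correlation
$1 - 10^{-10}$.

## Two-layer mixing

Per GWAS, the 102 candidates are tuned on one training cohort by
covariate-adjusted logistic likelihood for prevalent disease (ties: smaller
$p$, then smaller $s$, then dense LD). Layer 1 mixes the tuned
ancestry-specific scores within each trait; layer 2 mixes the trait-level
combined scores; each layer runs bidirectional stepwise AIC starting from
the full model (the single add/drop move with the largest AIC reduction,
stopping when none reduces it — verified against exhaustive subset search on
orthogonal designs) followed by one logistic fit whose score coefficients
are the mixing weights. Every mixing regression predicts the *disease*, also
for risk-factor trait scores; the baseline covariates (age, sex, array, ten
PCs) are included in all selection and mixing fits but never flattened.
Negative mixing weights are allowed — a trait score may enter protectively.
The disease's own layer-1 score always participates in layer 2 even if the
stepwise search would drop it, so the final score is never a pure
risk-factor construct. One training cohort serves tuning, selection and
mixing sequentially; separation, if it occurs, falls back to a tiny-ridge
($10^{-6}$) IRLS fit with a warning.

## Evaluation battery

All association models adjust for age, sex, genotyping array and ten PCs
unless a fixture has no such columns. OR/SD comes from logistic regression
on prevalent disease, HR/SD from a Cox model on the incident subset
(prevalent cases excluded, Efron ties), both with Wald intervals.
Percentile analyses rank ascending with stable ties into 100 bins.
Tail scans compare progressively wider tail groups against the middle
quintile (percentiles 41–60) in covariate-adjusted logistic models and
report the widest tail whose odds-ratio *point estimate* still meets the
fold threshold, stopping at the first failure; the middle quintile is a
fixed reference whose members are excluded from the tail group, otherwise
the reference empties beyond the 40th percentile. The risk-equivalence
search applies the same scan logic with a three-group Cox model and a
comparator condition, returning the widest top-percentile group whose
hazard-ratio point estimate reaches the comparator's (point-estimate
crossing; the original text does not define the criterion, and CI-overlap
rules would make the answer depend on the comparator group's size).

Nagelkerke $\Delta R^2$ follows
$R^2 = \frac{1 - e^{(2/n)(\ell_0-\ell_1)}}{1 - e^{(2/n)\ell_0}}$ for full
versus baseline models. The liability-scale $R^2$ maps the
*linear-probability* (observed-scale) $\Delta R^2$ through the standard
case-control ascertainment correction
$R^2_{liab} = R^2_{obs} C / (1 + R^2_{obs}\,\theta C)$ with
$C = \frac{K(1-K)}{z^2}\frac{K(1-K)}{P(1-P)}$ and
$\theta = m\frac{P-K}{1-K}\big(m\frac{P-K}{1-K}-t\big)$; feeding the
Nagelkerke value into this formula overstates the result (an early draft
did, and produced liability $R^2$ above the simulated heritability). The
transformation is checked against an independent in-test implementation and
is strictly increasing in its input. Harrell's C and its asymptotic
variance are delegated to `survival::concordance` and verified against
$O(n^2)$ pair enumeration. NRI uses the category-crossing definition at the
7.5% threshold (continuous version: sign of any change) with percentile
bootstrap CIs over individuals (default 100 resamples, seeded); the
categorical components satisfy the additive identity to $10^{-12}$ by
construction. The integrated model is a Cox fit on score, clinical risk
(probability scale, as delivered — configurable), their product and the ten
PCs; 10-year incidence surfaces use the Breslow baseline cumulative hazard
(the original figure's estimator is unstated; Breslow is the `survival`
default and the only one exposed by `basehaz`) on a grid of score
percentiles × the four conventional clinical-risk strata, other covariates
held at their means.

## The synthetic world

The generator emulates the statistical structure the pipeline needs, not
human genetics in full. Its defaults: 3 ancestries, ~2,000 variants in 40
blocks of 30–70, AR(1) within-block correlation with adjacent-variant
correlation $e^{-0.25} \approx 0.78$, ancestry divergence 0.5 (LD damping up
to 50%, frequency shifts of Balding–Nichols magnitude $F_{ST} \approx
0.05$), causal fraction 0.05, $h^2 = 0.3$ per trait, cross-ancestry effect
correlation 0.8, cross-trait 0.5, prevalence 5%, exponential incident
hazard $0.004\,e^{0.5 G_{std} + 0.5 C_{std}}$ per year censored at 12 years
(a typical biobank median follow-up), and 20,000-sample discovery, training
and validation cohorts. Prevalent disease is a liability threshold: latent
liability = genetic score + $N(0, 1-h^2)$, case above the $(1-K)$ quantile.
The clinical 10-year risk column is a logistic function of age, sex and two
simulated risk-factor traits — it plays the *role* of an external clinical
estimator; no published clinical equation is implemented.

Genotypes come from a latent-Gaussian threshold model: each haplotype is a
multivariate normal thresholded at $\Phi^{-1}(f)$, dosage = sum of two
haplotypes. The latent correlation is calibrated per variant pair by
inverting the bivariate-normal orthant probability (vectorised bisection
over a Gauss–Legendre quadrature of $\partial\Phi_2/\partial\rho$), so the
*realized* dosage correlation — which is what the panel documents — matches
the AR(1) proposal wherever the proposal is attainable; pairs beyond the
Fréchet bound for their frequencies are clipped to the nearest attainable
value. Ancestral frequencies follow a logit random walk within a block and
divergence shifts them with a shared block-level component, because
independent per-variant redraws would break the frequency similarity that
strong LD implies and make high targets unattainable. What a green test
does **not** establish: realism of demographic history, admixture,
imputation error, relatedness, X chromosome, or any particular human
population pair — divergence is a free parameter, as the quantitative
frequency differences of the original cohorts are not published in usable
form.

PCs are simulated as ancestry-offset noise rather than computed from the
genotypes: they exercise the adjustment and residualization code paths at a
fraction of the cost, but they do not carry real population structure, so
tests involving PC adjustment only establish mechanics, not confounding
control.

## Fixture scales and the directional claim

Test fixtures are scaled to a 1-CPU budget (hundreds of variants, thousands
of samples); the package default config keeps the stated full fixture. Two
calibration-sensitive choices are worth recording. The heritability-recovery
check uses a polygenic architecture (causal fraction 0.2): LD-score
regression assumes polygenicity, and sparse architectures at $M = 2000$ make
single-seed estimates swing by $\pm 0.3$. The multi-ancestry-gain check
draws discovery GWAS cohorts *disjoint* from the training cohort (running
GWAS on the training cohort hands the in-sample single-ancestry candidate an
artificial advantage), uses a strongly polygenic architecture (causal
fraction 0.5) so no single GWAS saturates at desk scale, and evaluates on
12,000 validation samples so paired hazard-ratio comparisons are not bound
by event noise. These mirror the regime of the study design the pipeline
reimplements — large external discovery GWAS, a large training biobank, a
polygenic trait — rather than tuning any acceptance threshold.

## Numerical choices and degenerate inputs

Eigenvalue clipping repairs near-PSD matrices (panel validation tolerates
eigenvalues $\ge -10^{-8}$). Variants with reference frequency outside
$[0.005, 0.995]$ are excluded from shrinkage to avoid per-allele scale
blow-up. Monomorphic variants get NA statistics, never silent removal.
Zero-variance candidate scores are skipped during tuning; all-degenerate
candidate sets error. Collinear PC columns are dropped with a warning; a
score with zero residual variance errors. Stage seeds derive from the run
seed by a fixed affine-mod scheme (`derive_seed`), so any stage reruns
independently and full runs are manifest-hash reproducible; all seeds stay
below $2^{31}$.

## Known limitations

No cross-block LD; no functional annotations in the prior; no penalized or
cross-validated mixing; no competing risks or time-varying covariates; the
flattened score reproduces the explicit combination exactly only within one
standardization group (per-ancestry standardization constants cannot be
folded into a single weight vector across groups); logistic GWAS covariate
adjustment is via a baseline-model offset, not a full joint fit.
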