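# mapgs — multi-ancestry, multi-trait polygenic scores

`mapgs` builds a genome-wide polygenic score for a disease by combining
evidence across ancestries and across genetically correlated traits, and then
evaluates the combined score with the statistical battery used in clinical
risk-prediction studies. It is aimed at statistical geneticists who want a
self-contained, fully testable implementation of this construction — every
stage can be exercised on synthetic cohorts generated by the package itself,
so no restricted biobank data are needed to run, test or extend the code.

## What it implements

**Shrinkage.** For each set of ancestry-stratified GWAS summary statistics
(per-variant marginal effect β̂ⱼ, standard error, sample size), posterior mean
effects are computed under a spike-and-slab prior with block linkage
disequilibrium:

    βⱼ ~ N(0, h²/(M·p))  with probability p,    βⱼ = 0  otherwise
    β̂ ~ N(R β, R/n)

where R is the block LD matrix from a reference panel. A Gibbs sampler
(Rcpp) residualizes each variant against its LD partners and accumulates the
Rao–Blackwellised posterior mean. The prior heritability is s·ĥ², with ĥ²
from LD-score regression (E[χ²ⱼ] = 1 + N·h²·ℓⱼ/M) and s a grid multiplier.
The candidate grid is 17 causal fractions × 3 heritability scales
(s ∈ {0.7, 1, 1.4}) × dense/sparsified LD = **102 candidates per GWAS**.

**Two-layer mixing.** Candidates are tuned per GWAS on a training cohort
(covariate-adjusted logistic likelihood for prevalent disease). Layer 1
combines the tuned ancestry-specific scores within each trait; layer 2
combines the trait-level scores. Both layers use bidirectional stepwise AIC
selection starting from the full model, then a logistic fit whose score
coefficients are the mixing weights β. The mixture is flattened back to a
single variant-level scoring file:

    wⱼ = Σₜ (β2ₜ/sdₜ) Σₐ (β1ₜₐ/sdₜₐ) wₜₐⱼ

**Evaluation.** OR/SD and HR/SD (covariate-adjusted logistic and Cox
models), Nagelkerke ΔR², liability-scale R² (case-control ascertainment
correction), Harrell's C, continuous and categorical NRI with bootstrap CIs,
100-bin percentile prevalence, tail-of-distribution odds scans against the
middle quintile, risk-equivalent percentile search, and an integrated
clinical×genetic Cox model with an interaction term and a Breslow-baseline
10-year incidence surface.

**Synthetic cohorts.** Block-AR(1) LD panels with ancestry divergence
(damped LD, Balding–Nichols-scale frequency shifts), genotypes from a
calibrated latent-Gaussian threshold model, shared causal effects with
cross-ancestry/cross-trait genetic correlations, a liability-threshold
prevalent-disease model, exponential incident event times and a clinical
10-year-risk column.

## Worked example

```r
library(mapgs)

cfg <- validate_config(list(
  name = "demo", seed = 11,
  simulation = list(ancestries = c("A1", "A2"), n_traits = 2, n_blocks = 15,
                    block_size_range = c(10, 20), n_gwas = 3000,
                    n_train = 3000, n_val = 3000,
                    prevalence_K = 0.1, incident_rate = 0.01),
  grid = list(causal_fractions = c(0.01, 0.1, 1), h2_scales = 1,
              sparse_flags = FALSE, gibbs_iterations = 150, burn_in = 150),
  evaluation = list(n_boot = 25)))

res <- run_pipeline(cfg, "runs/demo")
print(res$report)
```

On this desk-scale fixture the run finishes in ~13 seconds and prints
(numbers from an actual run of the configuration above):

```
eval_report with metrics: or_sd, hr_sd, liability_r2, harrell_c, nri, ...
  OR/SD 2.704 (2.378-3.075) p=4.79e-52
  HR/SD 1.687 (1.523-1.869) p=1.16e-23
  liability R2 0.2652
  Harrell C 0.6474 (0.6183-0.6766)
  categorical NRI 0.0267 (event 0.0251, non-event 0.0015)
```

OR/SD ≈ 2.7 means one standard deviation of the combined score multiplies
the odds of prevalent disease by ~2.7 in held-out validation samples;
HR/SD is the analogous hazard ratio for incident events; Harrell's C is the
probability that, of two comparable individuals, the one with the higher
score fails first; the liability R² of 0.27 sits below the simulated
heritability of 0.30, as it must. The run directory
contains every intermediate artifact — panels, summary statistics, scoring
files, mixing models, evaluation tables — plus a hash manifest: rerunning
the same config and seed reproduces every hash.

A command-line front end with the same stages is installed at
`inst/cli/mapgs` (`mapgs run --config cfg.json --out rundir`, plus
`simulate`, `shrink`, `score`, `evaluate` subcommands).

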