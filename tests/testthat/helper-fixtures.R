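# Shared fixtures, built once per test run and memoised. Everything is
# generated in code under fixed seeds; no data files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a single-ancestry panel: 20 blocks of 4-10 variants, ~140 variants
fix_panel <- function() fixture("panel", function() {
  simulate_ld_panel(n_blocks = 20, block_size_range = c(4, 10),
                    decay_param = 0.25, ancestry_divergence = 0, seed = 101,
                    ancestry = "EUR")
})

# two diverged ancestries sharing variants
fix_panel_set <- function() fixture("panel_set", function() {
  simulate_ld_panel_set(c("EUR", "AFR"), n_blocks = 20,
                        block_size_range = c(4, 10), decay_param = 0.25,
                        ancestry_divergence = 0.5, seed = 102)
})

fix_effects <- function() fixture("effects", function() {
  simulate_true_effects(list(EUR = fix_panel()), p_causal = 0.3, h2 = 0.4,
                        n_traits = 2, rg_trait = 0.5, seed = 103)
})

# one modest training cohort with phenotypes (n = 2500)
fix_cohort <- function() fixture("cohort", function() {
  simulate_cohort(fix_panel(), 2500, fix_effects(), seed = 104,
                  prevalence_K = 0.1, incident_rate = 0.01)
})

fix_sumstats <- function() fixture("sumstats", function() {
  run_gwas(fix_cohort(), "prevalent_case", "logistic")
})

# identity-LD panel of M variants at freq 0.5 for closed-form oracles
identity_panel <- function(M, freq = 0.5, ancestry = "X") {
  v <- data.frame(id = sprintf("v%04d", seq_len(M)), chr = 1L,
                  pos = seq_len(M), a1 = "A", a2 = "G", freq = freq,
                  stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(M), function(j)
    list(variants = v[j, , drop = FALSE], R = matrix(1, 1, 1)))
  ld_panel(ancestry, blocks)
}

# sumstats with prescribed marginal effects on an identity panel
make_sumstats <- function(ids, beta, se, n, ea = "A", oa = "G", eaf = 0.5) {
  data.frame(variant_id = ids, chr = 1L, pos = seq_along(ids),
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
             n = n, n_cases = NA_integer_, stringsAsFactors = FALSE)
}

# minimal synthetic cohort object wrapping a given phenotype table (no
# genotypes), for evaluation-layer tests
make_eval_cohort <- function(pheno, ancestry = "SYN") {
  for (k in paste0("PC", 1:10)) if (is.null(pheno[[k]])) pheno[[k]] <- 0
  if (is.null(pheno$ancestry)) pheno$ancestry <- ancestry
  structure(list(pheno = pheno, ancestry = ancestry), class = "cohort")
}

# covariate-free evaluation defaults keep degenerate fixtures out of glm
no_covs <- character(0)

with_fixed_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# exact mixture-posterior mean for a <=4-variant single-block spike-and-slab
# model: enumerate causal configurations, each a conjugate multivariate
# normal. Independent oracle for the Gibbs sampler.
enumerate_posterior_mean <- function(R, beta_hat, n, sigma2, p) {
  m <- length(beta_hat)
  configs <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  num <- rep(0, m)
  den <- 0
  for (i in seq_len(nrow(configs))) {
    c_ <- unlist(configs[i, ])
    k <- sum(c_)
    Sig <- diag(ifelse(c_, sigma2, 0), m)
    V <- R %*% Sig %*% R + R / n
    # guard: with no causal variants V = R/n
    ld <- determinant(V, logarithm = TRUE)
    q <- drop(crossprod(beta_hat, solve(V, beta_hat)))
    logw <- k * log(p) + (m - k) * log(1 - p + (p == 1)) -
      0.5 * as.numeric(ld$modulus) - 0.5 * q
    w <- exp(logw)
    mu <- if (k > 0) drop(Sig %*% R %*% solve(V, beta_hat)) else rep(0, m)
    num <- num + w * mu
    den <- den + w
  }
  num / den
}
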