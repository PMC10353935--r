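# Phenotypes: liability-threshold prevalent disease, exponential incident
# event times, quantitative risk-factor traits and a clinical 10-year risk
# column.

#' Default clinical risk model
#'
#' The clinical 10-year risk column is a logistic function of age, sex and
#' two quantitative risk-factor traits, standing in for an external clinical
#' estimator whose output the pipeline consumes as-is. Coefficients are on
#' the logit scale; `intercept` sets the marginal risk level.
#'
#' @param intercept logit-scale intercept.
#' @param age,sex,trait coefficients for standardized age, sex (0/1) and each
#'   risk-factor trait.
#' @return list of coefficients.
#' @export
clinical_model <- function(intercept = -2.8, age = 0.8, sex = 0.5,
                           trait = c(0.4, 0.3)) {
  list(intercept = intercept, age = age, sex = sex, trait = trait)
}

#' Simulate phenotypes, outcomes and covariates for a cohort
#'
#' The disease trait follows a liability-threshold model: liability = genetic
#' score (variance h2 by construction) + independent normal noise with
#' variance 1 - h2; a sample is a prevalent case when liability exceeds the
#' (1 - K) standard-normal quantile. For non-prevalent samples an incident
#' event time is drawn from an exponential distribution whose log hazard is
#' `log(incident_rate) + hazard_per_sd * G + clinical_hazard_coef * C`, where
#' G is the standardized genetic score and C the standardized clinical linear
#' predictor; events are administratively censored at `followup_years`.
#' Quantitative risk-factor traits (traits 2..T of `effects`) are their
#' genetic scores plus N(0, 1 - h2) noise. Age, sex, genotyping array and ten
#' ancestry principal components are simulated covariates; the PCs are
#' ancestry-group offsets plus unit noise, emulating the role (not the
#' computation) of genotype PCs.
#'
#' @param dosages n x M dosage matrix (variant-id column names).
#' @param effects a `true_effects` object; trait 1 is the disease trait.
#' @param panel `ld_panel` for this cohort's ancestry.
#' @param prevalence_K disease prevalence in (0, 1).
#' @param incident_rate baseline exponential hazard per year (> 0).
#' @param followup_years administrative censoring horizon (default 12).
#' @param clinical list from [clinical_model()].
#' @param hazard_per_sd log-hazard slope per SD of genetic score.
#' @param clinical_hazard_coef log-hazard slope per SD of the clinical linear
#'   predictor (ties the clinical risk column to actual risk).
#' @param ancestry_index integer used to offset the simulated PCs per group.
#' @param seed integer seed.
#' @return a `cohort`: list with `dosages`, `pheno` (data.frame), `ancestry`,
#'   `panel`. `pheno` carries sample_id, ancestry, age, sex, array, PC1..PC10,
#'   trait columns, prevalent_case, incident_case, follow_up_time,
#'   clinical_risk_10yr, and the true liability/genetic score for diagnostics.
#' @export
simulate_phenotypes <- function(dosages, effects, panel, prevalence_K,
                                incident_rate, followup_years = 12,
                                clinical = clinical_model(),
                                hazard_per_sd = 0.5,
                                clinical_hazard_coef = 0.5,
                                ancestry_index = 1L, seed) {
  assert_that(prevalence_K > 0 && prevalence_K < 1, "prevalence K must lie in (0, 1)")
  assert_that(incident_rate > 0, "incident_rate must be > 0")
  assert_that(all(effects$h2 < 1), "h2 of effects must be < 1")
  n <- nrow(dosages)
  n_traits <- dim(effects$beta)[3]
  with_seed(seed, {
    G <- genetic_score(dosages, effects, panel, trait = 1)
    h2 <- effects$h2[1]
    liability <- G + stats::rnorm(n, 0, sqrt(max(1 - h2, 0)))
    prevalent <- as.integer(liability > stats::qnorm(1 - prevalence_K))
    Gsd <- stats::sd(G)
    Gstd <- if (Gsd > 0) (G - mean(G)) / Gsd else rep(0, n)

    traits <- matrix(0, n, max(n_traits - 1, 0))
    if (n_traits > 1) {
      for (t in 2:n_traits) {
        gt <- genetic_score(dosages, effects, panel, trait = t)
        traits[, t - 1] <- gt + stats::rnorm(n, 0, sqrt(max(1 - effects$h2[t], 0)))
      }
      colnames(traits) <- paste0("trait", 2:n_traits)
    }

    age <- stats::rnorm(n, 57, 8)
    sex <- stats::rbinom(n, 1, 0.46)
    array <- sample(c("array_a", "array_b"), n, replace = TRUE, prob = c(0.8, 0.2))
    pcs <- matrix(stats::rnorm(n * 10), n, 10) +
      matrix(rep(ancestry_offsets(ancestry_index), each = n), n, 10)
    colnames(pcs) <- paste0("PC", 1:10)

    # clinical linear predictor and 10-year risk column
    ct <- clinical$trait
    lp <- clinical$intercept + clinical$age * (age - 57) / 8 + clinical$sex * sex
    k <- min(length(ct), ncol(traits))
    if (k > 0) lp <- lp + as.vector(traits[, seq_len(k), drop = FALSE] %*% ct[seq_len(k)])
    clinical_risk <- stats::plogis(lp)
    lp_sd <- stats::sd(lp)
    lp_std <- if (lp_sd > 0) (lp - mean(lp)) / lp_sd else rep(0, n)

    rate <- incident_rate * exp(hazard_per_sd * Gstd + clinical_hazard_coef * lp_std)
    event_time <- stats::rexp(n, rate)
    incident <- as.integer(event_time <= followup_years & prevalent == 0L)
    follow <- pmin(event_time, followup_years)
    follow[prevalent == 1L] <- followup_years   # not used in incident analyses

    pheno <- data.frame(
      sample_id = sprintf("%s_%06d", panel$ancestry, seq_len(n)),
      ancestry = panel$ancestry,
      age = age, sex = sex, array = array,
      pcs,
      prevalent_case = prevalent,
      incident_case = incident,
      follow_up_time = pmax(follow, 1e-6),
      clinical_risk_10yr = clinical_risk,
      true_genetic_score = G,
      true_liability = liability,
      stringsAsFactors = FALSE)
    if (n_traits > 1) pheno <- cbind(pheno, traits)
    rownames(dosages) <- pheno$sample_id
    structure(list(dosages = dosages, pheno = pheno,
                   ancestry = panel$ancestry, panel = panel),
              class = "cohort")
  })
}

ancestry_offsets <- function(idx) {
  base <- c(3, -2, 1.5, -1, 0.8, -0.5, 0.4, -0.3, 0.2, -0.1)
  base * (idx - 1)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %s, %d samples x %d variants, %d prevalent, %d incident\n",
              x$ancestry, nrow(x$pheno), ncol(x$dosages),
              sum(x$pheno$prevalent_case), sum(x$pheno$incident_case)))
  invisible(x)
}

#' Simulate a full cohort for one ancestry
#'
#' Convenience wrapper: genotypes from the panel, then phenotypes.
#'
#' @inheritParams simulate_phenotypes
#' @param panel an `ld_panel`.
#' @param n samples.
#' @param ... passed to [simulate_phenotypes()].
#' @param seed integer seed (genotypes use `seed`, phenotypes `seed + 1`).
#' @return a `cohort`.
#' @export
simulate_cohort <- function(panel, n, effects, seed, ...) {
  d <- simulate_genotypes(panel, n, seed = seed)
  simulate_phenotypes(d, effects, panel, seed = derive_seed(seed, 1), ...)
}

#' Baseline covariate column names
#'
#' Age, sex, genotyping array and the first ten principal components — the
#' standard adjustment set for every association model in the package.
#'
#' @return character vector of column names.
#' @export
baseline_covariates <- function() c("age", "sex", "array", paste0("PC", 1:10))

#' Write cohort phenotype/covariate table and dosages to TSV
#'
#' @param cohort a `cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$pheno, file.path(dir, "pheno.tsv"), sep = "\t")
  dt <- data.table::as.data.table(cohort$dosages)
  dt <- cbind(data.table::data.table(sample_id = cohort$pheno$sample_id), dt)
  data.table::fwrite(dt, file.path(dir, "dosages.tsv"), sep = "\t")
  invisible(dir)
}
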