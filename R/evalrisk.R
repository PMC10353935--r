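# The clinical evaluation battery: association effect sizes, variance
# explained, percentile and tail analyses, risk-equivalence search,
# discrimination, reclassification and the integrated clinical x genetic
# model.

eval_formula <- function(lhs, covariates, extra) {
  rhs <- c(covariates, extra)
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

#' Odds ratio per SD of score (prevalent disease)
#'
#' Covariate-adjusted logistic regression of the prevalent outcome on the
#' standardized score; returns the exponentiated score coefficient with Wald
#' CI and p-value.
#'
#' @param score standardized score vector.
#' @param cohort a `cohort` (uses `prevalent_case` and covariates).
#' @param covariates covariate columns (default [baseline_covariates()]).
#' @return list: `or`, `ci` (length 2), `p`, `beta`, `se`.
#' @export
odds_per_sd <- function(score, cohort, covariates = baseline_covariates()) {
  assert_that(stats::sd(score) > 1e-12, "score has zero variance")
  dat <- cbind(cohort$pheno, gps = score)
  covariates <- usable_covariates(dat, covariates)
  fit <- stats::glm(eval_formula("prevalent_case", covariates, "gps"),
                    family = stats::binomial(), data = dat)
  co <- summary(fit)$coefficients["gps", ]
  list(or = exp(co[1]), ci = exp(co[1] + c(-1, 1) * 1.96 * co[2]),
       p = unname(co[4]), beta = unname(co[1]), se = unname(co[2]))
}

# drop factor covariates with a single level (degenerate in small fixtures)
usable_covariates <- function(dat, covariates) {
  keep <- vapply(covariates, function(cv) {
    x <- dat[[cv]]
    if (is.character(x) || is.factor(x)) length(unique(x)) > 1
    else stats::sd(x) > 0
  }, TRUE)
  covariates[keep]
}

#' Hazard ratio per SD of score (incident disease)
#'
#' Cox proportional-hazards fit on the incident-analysis subset (prevalent
#' cases excluded), Efron tie handling, Wald inference.
#'
#' @inheritParams odds_per_sd
#' @return list: `hr`, `ci`, `p`, `beta`, `se`, `n_events`.
#' @export
hazard_per_sd <- function(score, cohort, covariates = baseline_covariates()) {
  dat <- cbind(cohort$pheno, gps = score)
  dat <- dat[dat$prevalent_case == 0, ]
  assert_that(all(dat$follow_up_time > 0), "follow-up times must be positive")
  assert_that(sum(dat$incident_case) > 0, "no events")
  covariates <- usable_covariates(dat, covariates)
  fit <- survival::coxph(
    eval_formula("survival::Surv(follow_up_time, incident_case)",
                 covariates, "gps"),
    data = dat, ties = "efron")
  co <- summary(fit)$coefficients["gps", ]
  list(hr = unname(exp(co["coef"])),
       ci = unname(exp(co["coef"] + c(-1, 1) * 1.96 * co["se(coef)"])),
       p = unname(co["Pr(>|z|)"]), beta = unname(co["coef"]),
       se = unname(co["se(coef)"]), n_events = sum(dat$incident_case))
}

#' Percentile ranks of a score
#'
#' Ascending score, ties broken by stable sample order; returns integer bins
#' 1..100 with each bin covering as close to 1% of samples as possible.
#'
#' @param score numeric vector (n >= 100).
#' @return integer vector of percentile bins.
#' @export
score_percentiles <- function(score) {
  n <- length(score)
  assert_that(n >= 100, "need at least 100 samples for percentile binning")
  rk <- rank(score, ties.method = "first")
  as.integer(ceiling(rk * 100 / n))
}

#' Unadjusted prevalence by score percentile
#'
#' 100 bins by score percentile; per-bin case fraction with Clopper-Pearson
#' binomial CI.
#'
#' @param score numeric score.
#' @param outcome 0/1 vector.
#' @return data.frame: percentile, n, cases, prevalence, lower, upper.
#' @export
percentile_prevalence <- function(score, outcome) {
  bins <- score_percentiles(score)
  tab <- lapply(1:100, function(b) {
    i <- bins == b
    k <- sum(outcome[i]); m <- sum(i)
    data.frame(percentile = b, n = m, cases = k,
               prevalence = if (m > 0) k / m else NA_real_,
               lower = if (m > 0) stats::qbeta(0.025, k, m - k + 1) else NA_real_,
               upper = if (m > 0) stats::qbeta(0.975, k + 1, m - k) else NA_real_)
  })
  do.call(rbind, tab)
}

middle_quintile <- function(bins) bins >= 41 & bins <= 60

#' Tail-fraction scan against the middle quintile
#'
#' For integer percentile cut-offs scanned from the extreme inward, fits a
#' covariate-adjusted logistic model of the outcome on membership in the tail
#' group versus the middle quintile (percentiles 41-60), and reports for each
#' fold threshold the largest tail fraction (in percent) whose odds-ratio
#' point estimate still meets the threshold. The scan is monotone: it stops
#' at the first cut-off that fails.
#'
#' @param score standardized score.
#' @param cohort a `cohort`.
#' @param fold_thresholds numeric vector, e.g. `c(3, 4, 5)` for the top tail
#'   or `c(1/3, 1/4, 1/5)` for the bottom tail.
#' @param direction "top" or "bottom".
#' @param covariates covariate columns.
#' @param max_fraction widest tail fraction scanned (default 80; the middle
#'   quintile always stays in the reference group, so beyond 40 the tail
#'   covers the non-middle-quintile mass).
#' @return data.frame: threshold, fraction (percent, 0 when even the extreme
#'   1% fails), or_at_fraction.
#' @export
tail_fraction_scan <- function(score, cohort, fold_thresholds = c(3, 4, 5),
                               direction = c("top", "bottom"),
                               covariates = baseline_covariates(),
                               max_fraction = 80L) {
  direction <- match.arg(direction)
  bins <- score_percentiles(score)
  mid <- middle_quintile(bins)
  y <- cohort$pheno$prevalent_case
  covariates <- usable_covariates(cohort$pheno, covariates)
  ors <- rep(NA_real_, max_fraction)
  for (x in seq_len(max_fraction)) {
    tail_i <- (if (direction == "top") bins > 100 - x else bins <= x) & !mid
    sel <- tail_i | mid
    dat <- cbind(cohort$pheno[sel, , drop = FALSE], tail_grp = as.integer(tail_i[sel]))
    fit <- tryCatch(stats::glm(eval_formula("prevalent_case", covariates, "tail_grp"),
                               family = stats::binomial(), data = dat),
                    error = function(e) NULL)
    if (!is.null(fit)) ors[x] <- exp(stats::coef(fit)["tail_grp"])
  }
  meets <- function(or, thr) {
    if (is.na(or)) return(FALSE)
    if (thr >= 1) or >= thr else or <= thr
  }
  out <- lapply(fold_thresholds, function(thr) {
    frac <- 0L
    for (x in seq_len(max_fraction)) {
      if (meets(ors[x], thr)) frac <- x else break
    }
    data.frame(threshold = thr, fraction = frac,
               or_at_fraction = if (frac > 0) ors[frac] else NA_real_)
  })
  do.call(rbind, out)
}

#' Risk-equivalent percentile threshold
#'
#' Finds the widest high-score group whose incident hazard matches that of a
#' comparator condition (for example, prevalent diabetes). A three-group Cox
#' model is fitted for each integer percentile x: comparator members,
#' comparator-free samples in the top x% of the score, and the middle
#' quintile (reference). Returns the largest x whose top-group hazard-ratio
#' point estimate is at least the comparator's; "none" (NA) when even x = 1
#' fails; the scan is monotone from the extreme inward.
#'
#' @param score standardized score.
#' @param cohort a `cohort`; incident analysis (prevalent cases excluded).
#' @param comparator_flag logical/0-1 vector aligned with the cohort rows.
#' @param covariates covariate columns.
#' @param max_percentile widest percentile scanned (default 80).
#' @return list: `percentile` (NA if none), `comparator_hr`, `top_hr_at`.
#' @export
risk_equivalent_threshold <- function(score, cohort, comparator_flag,
                                      covariates = baseline_covariates(),
                                      max_percentile = 80L) {
  keep <- cohort$pheno$prevalent_case == 0
  dat0 <- cohort$pheno[keep, , drop = FALSE]
  sc <- score[keep]
  cmp <- as.logical(comparator_flag)[keep]
  assert_that(any(cmp), "comparator group is empty")
  bins <- score_percentiles(sc)
  mid <- middle_quintile(bins) & !cmp
  covariates <- usable_covariates(dat0, covariates)
  res_pct <- NA_integer_
  cmp_hr <- NA_real_
  top_hr <- NA_real_
  for (x in seq_len(max_percentile)) {
    top <- bins > 100 - x & !cmp & !mid
    sel <- cmp | top | mid
    grp <- factor(ifelse(cmp, "comparator", ifelse(top, "top", "mid"))[sel],
                  levels = c("mid", "comparator", "top"))
    dat <- cbind(dat0[sel, , drop = FALSE], grp = grp)
    fit <- tryCatch(survival::coxph(
      eval_formula("survival::Surv(follow_up_time, incident_case)",
                   covariates, "grp"), data = dat, ties = "efron"),
      error = function(e) NULL)
    if (is.null(fit)) break
    cf <- stats::coef(fit)
    hr_cmp <- exp(unname(cf["grpcomparator"]))
    hr_top <- exp(unname(cf["grptop"]))
    if (x == 1) cmp_hr <- hr_cmp
    if (is.na(hr_top) || hr_top < hr_cmp) break
    res_pct <- x
    top_hr <- hr_top
    cmp_hr <- hr_cmp
  }
  list(percentile = res_pct, comparator_hr = cmp_hr, top_hr_at = top_hr)
}

#' Nagelkerke pseudo-R-squared gain of a score
#'
#' R2 = (1 - exp((2/n)(logL0 - logL1))) / (1 - exp((2/n) logL0)) for the full
#' model (covariates + score) and the baseline (covariates only); the
#' difference is returned.
#'
#' @inheritParams odds_per_sd
#' @param outcome_col outcome column (default prevalent_case).
#' @return list: `delta_r2`, `r2_full`, `r2_base`.
#' @export
delta_nagelkerke_r2 <- function(score, cohort,
                                covariates = baseline_covariates(),
                                outcome_col = "prevalent_case") {
  dat <- cbind(cohort$pheno, gps = score)
  covariates <- usable_covariates(dat, covariates)
  f1 <- stats::glm(eval_formula(outcome_col, covariates, "gps"),
                   family = stats::binomial(), data = dat)
  f0 <- stats::glm(eval_formula(outcome_col, covariates, NULL),
                   family = stats::binomial(), data = dat)
  n <- nrow(dat)
  l1 <- as.numeric(stats::logLik(f1))
  l0 <- as.numeric(stats::logLik(f0))
  lnull <- as.numeric(stats::logLik(
    stats::glm(eval_formula(outcome_col, NULL, "1"),
               family = stats::binomial(), data = dat)))
  nagel <- function(lfull) (1 - exp((2 / n) * (lnull - lfull))) /
    (1 - exp((2 / n) * lnull))
  r2_full <- nagel(l1)
  r2_base <- nagel(l0)
  list(delta_r2 = r2_full - r2_base, r2_full = r2_full, r2_base = r2_base)
}

#' Observed-scale R2 transformed to the liability scale
#'
#' The case-control ascertainment correction for logistic models (Lee et al.
#' style): with population prevalence K, sample case fraction P, threshold
#' t = qnorm(1 - K), z = dnorm(t) and m = z / K,
#' C = K(1-K)/z^2 * K(1-K)/(P(1-P)) and
#' theta = m (P-K)/(1-K) * (m (P-K)/(1-K) - t); then
#' R2_liab = R2_obs C / (1 + R2_obs theta C). Strictly increasing in R2_obs
#' at fixed (K, P), and 0 at 0.
#'
#' @param r2_obs observed-scale R2 difference attributable to the score.
#' @param prevalence_K population prevalence in (0, 1).
#' @param case_fraction_P sample case fraction in (0, 1).
#' @return liability-scale R2.
#' @export
liability_r2_transform <- function(r2_obs, prevalence_K, case_fraction_P) {
  assert_that(prevalence_K > 0 && prevalence_K < 1, "K must lie in (0, 1)")
  K <- prevalence_K; P <- case_fraction_P
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  r2_obs * C / (1 + r2_obs * theta * C)
}

#' Liability-scale R2 of a score in a cohort
#'
#' The observed-scale R2 gain of the score (difference in linear-probability
#' R2 between the covariate+score and covariate-only models, the input scale
#' the ascertainment correction is defined for) is mapped to the liability
#' scale with the population prevalence and the cohort's case fraction.
#'
#' @inheritParams odds_per_sd
#' @param prevalence_K population prevalence.
#' @return list: `liability_r2`, `delta_r2_obs`, `case_fraction`.
#' @export
liability_r2 <- function(score, cohort, prevalence_K,
                         covariates = baseline_covariates()) {
  dat <- cbind(cohort$pheno, gps = score)
  covariates <- usable_covariates(dat, covariates)
  f1 <- stats::lm(eval_formula("prevalent_case", covariates, "gps"), data = dat)
  f0 <- stats::lm(eval_formula("prevalent_case", covariates, NULL), data = dat)
  d <- summary(f1)$r.squared - summary(f0)$r.squared
  P <- mean(cohort$pheno$prevalent_case)
  list(liability_r2 = liability_r2_transform(d, prevalence_K, P),
       delta_r2_obs = d, case_fraction = P)
}

#' Harrell's C-statistic
#'
#' Concordance over usable (comparable-under-censoring) pairs, ties in the
#' prediction counting 0.5, with the standard asymptotic variance for the CI.
#' Higher predictions must indicate higher risk (earlier failure).
#'
#' @param predictions numeric risk predictions.
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return list: `c`, `se`, `ci`.
#' @export
harrell_c <- function(predictions, time, event) {
  fit <- survival::concordance(survival::Surv(time, event) ~ predictions,
                               reverse = TRUE)
  se <- sqrt(fit$var)
  list(c = unname(fit$concordance), se = unname(se),
       ci = unname(fit$concordance + c(-1, 1) * 1.96 * se))
}

#' Net reclassification improvement
#'
#' Categorical NRI at a risk threshold: two classes split at `threshold`;
#' event component = P(up | event) - P(down | event); non-event component =
#' P(down | non-event) - P(up | non-event); overall = sum. Continuous NRI
#' uses the sign of any risk change. Percentile bootstrap CIs over
#' individuals (default 100 resamples), seeded.
#'
#' @param old_risk,new_risk predicted risks in [0, 1].
#' @param outcome 0/1 vector.
#' @param threshold risk threshold (default 0.075).
#' @param n_boot bootstrap resamples (default 100).
#' @param seed integer seed for the bootstrap.
#' @return list with `categorical` and `continuous`, each holding `overall`,
#'   `event`, `non_event` and bootstrap `ci_*` fields.
#' @export
net_reclassification <- function(old_risk, new_risk, outcome,
                                 threshold = 0.075, n_boot = 100L, seed = 1L) {
  assert_that(all(old_risk >= 0 & old_risk <= 1) &&
                all(new_risk >= 0 & new_risk <= 1), "risks must lie in [0, 1]")
  point <- nri_components(old_risk, new_risk, outcome, threshold)
  boots <- with_seed(seed, {
    n <- length(outcome)
    replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      unlist(nri_components(old_risk[i], new_risk[i], outcome[i], threshold))
    })
  })
  ci <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  add_ci <- function(comp, prefix) {
    comp$ci_overall <- unname(ci[, paste0(prefix, ".overall")])
    comp$ci_event <- unname(ci[, paste0(prefix, ".event")])
    comp$ci_non_event <- unname(ci[, paste0(prefix, ".non_event")])
    comp
  }
  list(categorical = add_ci(point$categorical, "categorical"),
       continuous = add_ci(point$continuous, "continuous"))
}

nri_components <- function(old_risk, new_risk, outcome, threshold) {
  ev <- outcome == 1
  cat_old <- old_risk >= threshold
  cat_new <- new_risk >= threshold
  up <- cat_new & !cat_old
  down <- !cat_new & cat_old
  cat_ev <- mean(up[ev]) - mean(down[ev])
  cat_ne <- mean(down[!ev]) - mean(up[!ev])
  cup <- new_risk > old_risk
  cdown <- new_risk < old_risk
  con_ev <- mean(cup[ev]) - mean(cdown[ev])
  con_ne <- mean(cdown[!ev]) - mean(cup[!ev])
  list(categorical = list(overall = cat_ev + cat_ne, event = cat_ev,
                          non_event = cat_ne),
       continuous = list(overall = con_ev + con_ne, event = con_ev,
                         non_event = con_ne))
}

#' Integrated clinical x genetic risk model
#'
#' Cox model of incident disease on the standardized score, the clinical
#' 10-year risk (probability scale), their product term and the ten principal
#' components. The baseline cumulative hazard uses the Breslow estimator, and
#' a predicted 10-year cumulative incidence surface is computed on a grid of
#' score percentiles by the four conventional clinical-risk strata (<5%,
#' 5-<7.5%, 7.5-<20%, >=20%), holding PCs at their means and using each
#' stratum's mean clinical risk.
#'
#' @param score standardized score.
#' @param clinical_risk 10-year risk column in [0, 1].
#' @param cohort a `cohort`; prevalent cases are excluded.
#' @param horizon prediction horizon in years (default 10).
#' @return list: `fit` (coxph), `interaction` (coef, se, p), `grid`
#'   (data.frame percentile x stratum with predicted incidence).
#' @export
integrated_risk_model <- function(score, clinical_risk, cohort, horizon = 10) {
  keep <- cohort$pheno$prevalent_case == 0
  dat <- cbind(cohort$pheno[keep, , drop = FALSE],
               gps = score[keep], clin = clinical_risk[keep])
  pcs <- paste0("PC", 1:10)
  form <- eval_formula("survival::Surv(follow_up_time, incident_case)",
                       pcs, c("gps", "clin", "gps:clin"))
  environment(form) <- environment()
  fit <- survival::coxph(form, data = dat, ties = "efron")
  co <- summary(fit)$coefficients
  inter <- co["gps:clin", ]
  strata <- cut(dat$clin, c(-Inf, 0.05, 0.075, 0.20, Inf),
                labels = c("low", "borderline", "intermediate", "high"),
                right = FALSE)
  bh <- suppressWarnings(survival::basehaz(fit, centered = TRUE))
  H0 <- stats::approx(bh$time, bh$hazard, xout = horizon, rule = 2)$y
  pct <- 1:100
  gps_grid <- stats::qnorm((pct - 0.5) / 100)
  means <- colMeans(dat[, pcs, drop = FALSE])
  ref <- data.frame(t(c(gps = mean(dat$gps), clin = mean(dat$clin), means)))
  grid <- do.call(rbind, lapply(levels(strata), function(sl) {
    i <- strata == sl
    if (!any(i)) return(NULL)
    cmean <- mean(dat$clin[i])
    nd <- ref[rep(1, length(pct)), ]
    nd$gps <- gps_grid
    nd$clin <- cmean
    lp <- stats::predict(fit, newdata = nd, type = "lp", reference = "sample")
    data.frame(percentile = pct, stratum = sl, clinical_risk = cmean,
               incidence = 1 - exp(-H0 * exp(lp)))
  }))
  list(fit = fit,
       interaction = list(coef = unname(inter["coef"]),
                          se = unname(inter["se(coef)"]),
                          p = unname(inter["Pr(>|z|)"])),
       grid = grid)
}

#' Assemble an evaluation report
#'
#' Bundles the battery's outputs into a single `eval_report` object with a
#' tabular summary; all stochastic inputs (the NRI bootstrap) record their
#' seed upstream. An empty call yields a valid empty report.
#'
#' @param ... named metric results (any subset of or_sd, hr_sd, delta_r2,
#'   liability_r2, harrell_c, nri, percentile_table, tail_table,
#'   risk_equivalent, integrated).
#' @return an `eval_report`.
#' @export
eval_report <- function(...) {
  metrics <- list(...)
  structure(list(metrics = metrics), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report with metrics:", paste(names(x$metrics), collapse = ", "), "\n")
  m <- x$metrics
  if (!is.null(m$or_sd))
    cat(sprintf("  OR/SD %.3f (%.3f-%.3f) p=%.3g\n", m$or_sd$or,
                m$or_sd$ci[1], m$or_sd$ci[2], m$or_sd$p))
  if (!is.null(m$hr_sd))
    cat(sprintf("  HR/SD %.3f (%.3f-%.3f) p=%.3g\n", m$hr_sd$hr,
                m$hr_sd$ci[1], m$hr_sd$ci[2], m$hr_sd$p))
  if (!is.null(m$liability_r2))
    cat(sprintf("  liability R2 %.4f\n", m$liability_r2$liability_r2))
  if (!is.null(m$harrell_c))
    cat(sprintf("  Harrell C %.4f (%.4f-%.4f)\n", m$harrell_c$c,
                m$harrell_c$ci[1], m$harrell_c$ci[2]))
  if (!is.null(m$nri))
    cat(sprintf("  categorical NRI %.4f (event %.4f, non-event %.4f)\n",
                m$nri$categorical$overall, m$nri$categorical$event,
                m$nri$categorical$non_event))
  invisible(x)
}

#' Write an evaluation report to a directory of TSV/JSON files
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- report$metrics
  scalars <- list()
  for (nm in names(m)) {
    x <- m[[nm]]
    if (is.data.frame(x)) {
      data.table::fwrite(x, file.path(dir, paste0(nm, ".tsv")), sep = "\t")
    } else scalars[[nm]] <- x
  }
  if (!is.null(scalars$integrated)) {
    data.table::fwrite(scalars$integrated$grid,
                       file.path(dir, "integrated_grid.tsv"), sep = "\t")
    scalars$integrated <- scalars$integrated["interaction"]
  }
  jsonlite::write_json(scalars, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  invisible(dir)
}
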