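# Evaluation battery: effect sizes, variance explained, percentile and tail
# analyses, discrimination, reclassification, integrated model.

sim_prev_cohort <- function(n, slope = 0, seed = 1, K = 0.1) {
  with_fixed_seed(seed, {
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(qlogis(K) + slope * s))
    list(score = s, cohort = make_eval_cohort(data.frame(prevalent_case = y)))
  })
}

sim_surv_cohort <- function(n, slope = 0, seed = 1, rate = 0.02, horizon = 12) {
  with_fixed_seed(seed, {
    s <- rnorm(n)
    t_ev <- rexp(n, rate * exp(slope * s))
    ph <- data.frame(prevalent_case = 0L,
                     incident_case = as.integer(t_ev <= horizon),
                     follow_up_time = pmin(t_ev, horizon))
    list(score = s, cohort = make_eval_cohort(ph))
  })
}

test_that("odds_per_sd recovers a generating slope and rejects constants", {
  d <- sim_prev_cohort(20000, slope = 0.5, seed = 501)
  res <- odds_per_sd(d$score, d$cohort, no_covs)
  expect_gt(res$ci[1], exp(0.5) * 0.9)
  expect_lt(res$ci[2], exp(0.5) * 1.1)
  expect_error(odds_per_sd(rep(1, 20000), d$cohort, no_covs), "zero variance")
})

test_that("hazard_per_sd recovers slope 0.5 and errors with no events", {
  d <- sim_surv_cohort(50000, slope = 0.5, seed = 502)
  res <- hazard_per_sd(d$score, d$cohort, no_covs)
  expect_gt(res$beta, 0.45)
  expect_lt(res$beta, 0.55)
  d0 <- sim_surv_cohort(100, slope = 0, seed = 503)
  d0$cohort$pheno$incident_case <- 0L
  expect_error(hazard_per_sd(d0$score, d0$cohort, no_covs), "no events")
})

test_that("OR and HR null CIs cover 1 at the nominal rate", {
  or_cover <- 0
  hr_cover <- 0
  for (r in 1:100) {
    d <- sim_prev_cohort(1000, slope = 0, seed = 600 + r)
    res <- odds_per_sd(d$score, d$cohort, no_covs)
    if (res$ci[1] <= 1 && 1 <= res$ci[2]) or_cover <- or_cover + 1
    ds <- sim_surv_cohort(1000, slope = 0, seed = 700 + r)
    rs <- hazard_per_sd(ds$score, ds$cohort, no_covs)
    if (rs$ci[1] <= 1 && 1 <= rs$ci[2]) hr_cover <- hr_cover + 1
  }
  expect_gte(or_cover, 90); expect_lte(or_cover, 99)
  expect_gte(hr_cover, 90); expect_lte(hr_cover, 99)
})

test_that("percentile binning: n = 100 gives one sample per bin; ties stable", {
  s <- c(rep(1, 50), rep(2, 50))
  bins <- score_percentiles(s)
  expect_equal(sort(unique(bins)), 1:100)
  expect_true(all(table(bins) == 1))
  # stable tie-break: earlier samples get lower percentiles
  expect_true(all(bins[1:50] <= 50))
})

test_that("percentile prevalence: null flatness and perfect separation", {
  set.seed(801)
  s <- rnorm(10000)
  y <- rbinom(10000, 1, 0.1)
  tab <- percentile_prevalence(s, y)
  expect_equal(nrow(tab), 100)
  expect_true(all(tab$n %in% c(100)))
  obs <- tab$cases
  expect_gt(chisq.test(cbind(obs, tab$n - obs))$p.value, 0.01)
  # perfectly separating score at 5% prevalence
  n <- 10000
  s2 <- seq_len(n)
  y2 <- as.integer(s2 > 0.95 * n)
  tab2 <- percentile_prevalence(s2, y2)
  expect_equal(tab2$prevalence[96:100], rep(1, 5))
  expect_equal(tab2$prevalence[1:95], rep(0, 95))
})

test_that("tail scan equals a brute-force scan on a deterministic fixture", {
  # outcome assigned deterministically by bin: known bin-wise odds
  n <- 10000
  s <- seq_len(n)
  bins <- score_percentiles(s)
  prev <- ifelse(bins > 95, 0.5, ifelse(bins > 85, 0.3, 0.1))
  set.seed(802)
  y <- rbinom(n, 1, prev)
  co <- make_eval_cohort(data.frame(prevalent_case = y))
  res <- tail_fraction_scan(s, co, fold_thresholds = c(3, 4), "top", no_covs)
  # independent brute-force scan with plain glm
  mid <- bins >= 41 & bins <= 60
  brute <- sapply(1:40, function(x) {
    tail_i <- bins > 100 - x
    sel <- tail_i | mid
    exp(coef(glm(y[sel] ~ tail_i[sel], family = binomial))[2])
  })
  for (k in seq_len(nrow(res))) {
    thr <- res$threshold[k]
    bf <- 0
    for (x in 1:40) if (!is.na(brute[x]) && brute[x] >= thr) bf <- x else break
    expect_equal(res$fraction[k], bf)
  }
})

test_that("tail scan reports 0 for a null score at threshold 3", {
  nulls <- 0
  for (r in 1:20) {
    set.seed(900 + r)
    s <- rnorm(4000)
    y <- rbinom(4000, 1, 0.1)
    co <- make_eval_cohort(data.frame(prevalent_case = y))
    res <- tail_fraction_scan(s, co, 3, "top", no_covs, max_fraction = 20L)
    if (res$fraction == 0) nulls <- nulls + 1
  }
  expect_gte(nulls, 19)
})

test_that("risk-equivalence: null comparator is matched almost everywhere", {
  set.seed(910)
  n <- 30000
  s <- rnorm(n)
  cmp <- rbinom(n, 1, 0.1)          # comparator with no extra hazard
  t_ev <- rexp(n, 0.02 * exp(0.4 * s))
  co <- make_eval_cohort(data.frame(
    prevalent_case = 0L, incident_case = as.integer(t_ev <= 12),
    follow_up_time = pmin(t_ev, 12)))
  res <- risk_equivalent_threshold(s, co, cmp, no_covs)
  expect_gte(res$percentile, 79)
  # a score with zero effect never reaches a strong comparator
  t2 <- rexp(n, 0.02 * exp(1.0 * cmp))
  co2 <- make_eval_cohort(data.frame(
    prevalent_case = 0L, incident_case = as.integer(t2 <= 12),
    follow_up_time = pmin(t2, 12)))
  s_null <- rnorm(n)
  res2 <- risk_equivalent_threshold(s_null, co2, cmp, no_covs)
  expect_true(is.na(res2$percentile))
})

test_that("risk-equivalence matches the truncated-normal crossing point", {
  # comparator log-hazard +1.0, score slope 0.5/SD: the top-x% group mean
  # satisfies E[s | top x] * 0.5 = 1.0 at the crossing
  set.seed(920)
  n <- 100000
  s <- rnorm(n)
  cmp <- rbinom(n, 1, 0.1)
  t_ev <- rexp(n, 0.01 * exp(0.5 * s + 1.0 * cmp))
  co <- make_eval_cohort(data.frame(
    prevalent_case = 0L, incident_case = as.integer(t_ev <= 12),
    follow_up_time = pmin(t_ev, 12)))
  res <- risk_equivalent_threshold(s, co, cmp, no_covs, max_percentile = 60L)
  # analytic: E[s | s > q] = dnorm(q)/(1 - pnorm(q)) = 2 at the crossing
  f <- function(q) dnorm(q) / (1 - pnorm(q)) - 2
  q_star <- uniroot(f, c(0.5, 3))$root
  x_star <- 100 * (1 - pnorm(q_star))
  expect_lt(abs(res$percentile - x_star), 3)
})

test_that("Nagelkerke delta-R2: null score, duplicate covariate, hand formula", {
  d <- sim_prev_cohort(50000, slope = 0, seed = 930)
  expect_lt(abs(delta_nagelkerke_r2(d$score, d$cohort, no_covs)$delta_r2),
            0.002)
  # duplicate covariate adds nothing
  d2 <- sim_prev_cohort(5000, slope = 0.5, seed = 931)
  d2$cohort$pheno$cov1 <- d2$score
  r <- suppressWarnings(delta_nagelkerke_r2(d2$score, d2$cohort, "cov1"))
  expect_lt(abs(r$delta_r2), 1e-8)
  # hand-computed 20-sample fixture
  y <- c(1, 0, 1, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 1, 0, 0)
  x <- c(2.1, -0.3, 1.5, 0.9, -1.2, 0.1, 1.8, -0.6, -0.9, 0.4,
         1.1, -1.5, 0.2, -0.2, -1.0, 2.4, -0.4, 0.8, -1.8, 0.3)
  co <- make_eval_cohort(data.frame(prevalent_case = y))
  r2 <- suppressWarnings(delta_nagelkerke_r2(x, co, no_covs))
  n <- 20
  l1 <- as.numeric(logLik(suppressWarnings(glm(y ~ x, family = binomial))))
  l0 <- as.numeric(logLik(glm(y ~ 1, family = binomial)))
  nag <- function(l) (1 - exp((2 / n) * (l0 - l))) / (1 - exp((2 / n) * l0))
  expect_equal(r2$delta_r2, nag(l1) - nag(l0), tolerance = 1e-10)
  expect_equal(r2$r2_full, nag(l1), tolerance = 1e-10)
})

test_that("liability transform: zero map, monotonicity, cross-implementation", {
  expect_equal(liability_r2_transform(0, 0.05, 0.5), 0)
  # independent re-implementation of the published correction
  K <- 0.05; P <- 0.5; R2O <- 0.10
  t <- qnorm(1 - K); z <- dnorm(t); m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  expect_equal(liability_r2_transform(R2O, K, P),
               R2O * C / (1 + R2O * theta * C), tolerance = 1e-10)
  # strictly increasing in observed R2
  vals <- sapply(seq(0, 0.3, by = 0.02), liability_r2_transform,
                 prevalence_K = 0.05, case_fraction_P = 0.3)
  expect_true(all(diff(vals) > 0))
  # continuity at K = P: small observed gain stays positive and finite
  v <- liability_r2_transform(0.01, 0.1, 0.1)
  expect_gt(v, 0); expect_true(is.finite(v))
})

test_that("Harrell's C: perfect concordance, ties, brute-force equality", {
  r <- harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(r$c, 1.0)
  expect_equal(harrell_c(rep(1, 50), rexp(50), rbinom(50, 1, 0.8))$c, 0.5)
  set.seed(940)
  n <- 200
  pred <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.3 * pred))
  event <- as.integer(time < 15); time <- pmin(time, 15)
  r <- harrell_c(pred, time, event)
  # O(n^2) pair enumeration
  conc <- 0; usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    first <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
    if (is.na(first)) next
    if (event[first] == 0) next      # earlier time censored: not comparable
    usable <- usable + 1
    d <- pred[first] - pred[c(i, j)[c(i, j) != first]]
    conc <- conc + if (d > 0) 1 else if (d == 0) 0.5 else 0
  }
  expect_equal(r$c, conc / usable, tolerance = 1e-12)
})

test_that("NRI: identity, hand count, additivity, printed components", {
  y <- rbinom(200, 1, 0.3)
  old <- runif(200, 0, 0.3)
  r <- net_reclassification(old, old, y, n_boot = 10, seed = 1)
  expect_equal(r$categorical$overall, 0)
  expect_equal(r$continuous$overall, 0)
  # toy table: 10 events (3 up, 1 down), 10 non-events (1 up, 2 down) —
  # up/down are category changes across the 7.5% threshold
  y2 <- rep(c(1, 0), each = 10)
  old2 <- rep(0.05, 20)
  old2[4] <- 0.2; old2[12:13] <- 0.2    # start above threshold
  new2 <- old2
  new2[1:3] <- 0.2; new2[4] <- 0.01     # events: 3 up, 1 down
  new2[11] <- 0.2; new2[12:13] <- 0.01  # non-events: 1 up, 2 down
  r2 <- net_reclassification(old2, new2, y2, threshold = 0.075,
                             n_boot = 10, seed = 2)
  expect_equal(r2$categorical$event, 0.2, tolerance = 1e-12)
  expect_equal(r2$categorical$non_event, 0.1, tolerance = 1e-12)
  expect_equal(r2$categorical$overall, 0.3, tolerance = 1e-12)
  # additive identity on random inputs
  for (r_ in 1:10) {
    set.seed(950 + r_)
    y3 <- rbinom(500, 1, 0.2)
    o3 <- runif(500); n3 <- pmin(pmax(o3 + rnorm(500, 0, 0.2), 0), 1)
    cc <- mapgs:::nri_components(o3, n3, y3, 0.075)$categorical
    expect_equal(cc$overall, cc$event + cc$non_event, tolerance = 1e-12)
  }
})

test_that("integrated model: null interaction calibration and sign recovery", {
  cover <- 0
  neg <- 0
  for (r in 1:25) {
    set.seed(960 + r)
    n <- 4000
    gps <- rnorm(n)
    clin <- runif(n, 0.01, 0.4)
    for (omega in c(0, -1.5)) {
      rate <- 0.02 * exp(0.4 * gps + 2 * clin + omega * gps * clin)
      t_ev <- rexp(n, rate)
      co <- make_eval_cohort(data.frame(
        prevalent_case = 0L, incident_case = as.integer(t_ev <= 12),
        follow_up_time = pmin(t_ev, 12)))
      # PCs are constant zero in this fixture; give them tiny noise so the
      # Cox fit is full rank
      for (k in paste0("PC", 1:10)) co$pheno[[k]] <- rnorm(n, 0, 1)
      res <- integrated_risk_model(gps, clin, co)
      ci <- res$interaction$coef + c(-1.96, 1.96) * res$interaction$se
      if (omega == 0 && ci[1] <= 0 && 0 <= ci[2]) cover <- cover + 1
      if (omega < 0 && res$interaction$coef < 0) neg <- neg + 1
    }
  }
  expect_gte(cover, 22)   # ~95% coverage of 25 replicates, with slack
  expect_gte(neg, 23)     # negative interaction recovered in >= 9/10
})

test_that("predicted incidence rises with score percentile within strata", {
  set.seed(990)
  n <- 8000
  gps <- rnorm(n)
  clin <- runif(n, 0.01, 0.4)
  t_ev <- rexp(n, 0.02 * exp(0.5 * gps + 2 * clin))
  co <- make_eval_cohort(data.frame(
    prevalent_case = 0L, incident_case = as.integer(t_ev <= 12),
    follow_up_time = pmin(t_ev, 12)))
  for (k in paste0("PC", 1:10)) co$pheno[[k]] <- rnorm(n, 0, 1)
  res <- integrated_risk_model(gps, clin, co)
  for (sl in unique(res$grid$stratum)) {
    g <- res$grid[res$grid$stratum == sl, ]
    total_effect <- res$fit$coefficients["gps"] +
      res$fit$coefficients["gps:clin"] * g$clinical_risk[1]
    if (total_effect > 0) expect_true(all(diff(g$incidence) >= 0))
  }
})

test_that("reports assemble, print and persist; empty report is valid", {
  r0 <- eval_report()
  expect_s3_class(r0, "eval_report")
  dir <- withr::local_tempdir()
  write_eval_report(r0, dir)
  expect_true(file.exists(file.path(dir, "metrics.json")))
  d <- sim_prev_cohort(2000, slope = 0.4, seed = 995)
  rep1 <- eval_report(or_sd = odds_per_sd(d$score, d$cohort, no_covs),
                      percentile_table = percentile_prevalence(
                        d$score, d$cohort$pheno$prevalent_case))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_eval_report(rep1, dir1)
  write_eval_report(rep1, dir2)
  expect_identical(readLines(file.path(dir1, "metrics.json")),
                   readLines(file.path(dir2, "metrics.json")))
  expect_output(print(rep1), "OR/SD")
})
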