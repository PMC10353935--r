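# Synthetic-cohort module: LD panels, genotypes, effects, phenotypes, GWAS.

test_that("LD panel construction honours the documented invariants", {
  ps <- fix_panel_set()
  for (pan in ps) {
    expect_s3_class(pan, "ld_panel")
    ids <- unlist(lapply(pan$blocks, function(b) b$variants$id))
    expect_false(anyDuplicated(ids) > 0)
    for (b in pan$blocks) {
      expect_lt(max(abs(b$R - t(b$R))), 1e-10)
      expect_equal(unname(diag(b$R)), rep(1, nrow(b$R)))
      expect_gte(min(eigen(b$R, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
      expect_true(all(b$variants$freq > 0 & b$variants$freq < 1))
    }
  }
  # shared variant ids, diverged correlations and frequencies
  expect_identical(panel_variants(ps[[1]])$id, panel_variants(ps[[2]])$id)
  expect_false(isTRUE(all.equal(panel_variants(ps[[1]])$freq,
                                panel_variants(ps[[2]])$freq)))
})

test_that("panel simulation is deterministic and validates inputs", {
  a <- simulate_ld_panel(3, c(2, 4), 0.3, 0, seed = 7)
  b <- simulate_ld_panel(3, c(2, 4), 0.3, 0, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_ld_panel(3, c(0, 4), 0.3, 0, seed = 1), "block size")
  expect_error(simulate_ld_panel(3, c(2, 4), -1, 0, seed = 1), "decay")
})

test_that("a size-1 block is the 1x1 identity", {
  pan <- simulate_ld_panel(4, c(1, 1), 0.5, 0, seed = 3)
  for (b in pan$blocks) expect_identical(b$R, matrix(1, 1, 1))
})

test_that("AR(1) proposal with adjacent correlation 0.9 appears where attainable", {
  # equal-frequency variants: the threshold calibration reproduces 0.9^|i-j|
  cal <- mapgs:::threshold_block(0.9^abs(outer(1:4, 1:4, "-")), rep(0.5, 4))
  expect_lt(max(abs(cal$R - 0.9^abs(outer(1:4, 1:4, "-")))), 1e-4)
})

test_that("genotypes reproduce the panel LD and frequencies", {
  pan <- fix_panel()
  g <- simulate_genotypes(pan, 50000, seed = 11)
  expect_true(all(g %in% 0:2))
  v <- panel_variants(pan)
  expect_lt(max(abs(colMeans(g) - 2 * v$freq)), 0.02)
  worst <- 0
  for (b in pan$blocks) {
    emp <- cor(g[, b$variants$id])
    worst <- max(worst, max(abs(emp - b$R)))
  }
  expect_lt(worst, 0.02)
  expect_identical(g, simulate_genotypes(pan, 50000, seed = 11))
})

test_that("frequency calibration holds at freq 0.5 and for rare variants", {
  v <- data.frame(id = c("c1", "r1"), chr = 1, pos = 1:2, a1 = "A", a2 = "G",
                  freq = c(0.5, 0.05), stringsAsFactors = FALSE)
  pan <- ld_panel("X", list(
    list(variants = v[1, ], R = matrix(1, 1, 1)),
    list(variants = v[2, ], R = matrix(1, 1, 1))))
  g <- simulate_genotypes(pan, 100000, seed = 12)
  expect_lt(abs(mean(g[, "c1"]) - 1.0), 0.01)
  expect_lt(abs(mean(g[, "r1"]) - 0.1), 0.01)
})

test_that("a two-variant block hits a target correlation of 0.8", {
  v <- data.frame(id = c("a", "b"), chr = 1, pos = 1:2, a1 = "A", a2 = "G",
                  freq = 0.5, stringsAsFactors = FALSE)
  cal <- mapgs:::threshold_block(matrix(c(1, 0.8, 0.8, 1), 2), c(0.5, 0.5))
  pan <- ld_panel("X", list(list(variants = v, R = cal$R, latent = cal$latent)))
  g <- simulate_genotypes(pan, 50000, seed = 13)
  expect_gt(cor(g)[1, 2], 0.75)
  expect_lt(cor(g)[1, 2], 0.85)
})

test_that("true effects: causal fraction, degenerate correlations, calibration", {
  ps <- fix_panel_set()
  M <- length(panel_variants(ps[[1]])$id)
  e_all <- simulate_true_effects(ps, p_causal = 1, h2 = 0.3, seed = 21)
  expect_equal(sum(e_all$causal), M)
  e_same <- simulate_true_effects(ps, p_causal = 0.5, h2 = 0.3, rg_anc = 1,
                                  seed = 22)
  # standardized effects identical across ancestries up to the per-ancestry
  # variance calibration scalar
  b1 <- e_same$beta[e_same$causal, 1, 1]
  b2 <- e_same$beta[e_same$causal, 2, 1]
  expect_gt(abs(cor(b1, b2)), 1 - 1e-10)
  expect_error(simulate_true_effects(ps, 0.5, 0.3,
                                     rg_anc = matrix(c(1, 2, 2, 1), 2),
                                     seed = 1),
               "positive semidefinite")
})

test_that("cross-ancestry effect correlation is recovered at M = 5000", {
  ps <- simulate_ld_panel_set(c("A", "B"), 250, c(10, 30), 0.3, 0.3, seed = 23)
  e <- simulate_true_effects(ps, p_causal = 0.5, h2 = 0.3, rg_anc = 0.8,
                             seed = 24)
  r <- cor(e$beta[e$causal, 1, 1], e$beta[e$causal, 2, 1])
  expect_gt(r, 0.75)
  expect_lt(r, 0.85)
})

test_that("realized genetic variance matches h2 after calibration", {
  pan <- fix_panel()
  eff <- fix_effects()
  g <- simulate_genotypes(pan, 30000, seed = 25)
  v <- var(genetic_score(g, eff, pan, trait = 1))
  expect_lt(abs(v - 0.4) / 0.4, 0.10)
})

test_that("null-genetics prevalence is calibrated to K", {
  pan <- identity_panel(30)
  eff <- simulate_true_effects(list(X = pan), p_causal = 1, h2 = 0, seed = 31)
  g <- simulate_genotypes(pan, 100000, seed = 32)
  co <- simulate_phenotypes(g, eff, pan, prevalence_K = 0.05,
                            incident_rate = 0.004, seed = 33)
  K <- 0.05
  expect_lt(abs(mean(co$pheno$prevalent_case) - K),
            3 * sqrt(K * (1 - K) / 100000))
  # prevalent cases never counted as incident
  expect_true(all(co$pheno$incident_case[co$pheno$prevalent_case == 1] == 0))
  expect_true(all(co$pheno$follow_up_time > 0))
  expect_true(all(co$pheno$clinical_risk_10yr >= 0 &
                    co$pheno$clinical_risk_10yr <= 1))
})

test_that("zero genetic hazard gives flat incidence across score quintiles", {
  pan <- identity_panel(30)
  eff <- simulate_true_effects(list(X = pan), p_causal = 1, h2 = 0.3, seed = 41)
  g <- simulate_genotypes(pan, 20000, seed = 42)
  co <- simulate_phenotypes(g, eff, pan, prevalence_K = 0.05,
                            incident_rate = 0.01, hazard_per_sd = 0,
                            clinical_hazard_coef = 0, seed = 43)
  ph <- co$pheno[co$pheno$prevalent_case == 0, ]
  q <- cut(ph$true_genetic_score, quantile(ph$true_genetic_score, 0:5 / 5),
           include.lowest = TRUE)
  rates <- tapply(ph$incident_case, q, mean)
  expect_gt(chisq.test(table(q, ph$incident_case))$p.value, 0.01)
  expect_lt(diff(range(rates)), 0.02)
})

test_that("incident hazard slope is recovered by a Cox fit", {
  pan <- fix_panel()
  eff <- fix_effects()
  co <- simulate_cohort(pan, 20000, eff, seed = 51, prevalence_K = 0.05,
                        incident_rate = 0.01, hazard_per_sd = 0.5,
                        clinical_hazard_coef = 0)
  ph <- co$pheno[co$pheno$prevalent_case == 0, ]
  gstd <- scale(ph$true_genetic_score)
  fit <- survival::coxph(survival::Surv(follow_up_time, incident_case) ~ gstd,
                         data = ph)
  expect_gt(coef(fit), log(1.568) - log(1.05))  # e^0.45
  expect_lt(coef(fit), log(1.649) + log(1.05))  # e^0.55, small slack for
  # the prevalent-exclusion truncation of the score distribution
})

test_that("GWAS null p-values are uniform and z-scores standard normal", {
  co <- fix_cohort()
  co$pheno$perm <- with_fixed_seed(61, sample(co$pheno$prevalent_case))
  ss <- run_gwas(co, "perm", "logistic")
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.03)
  expect_gt(ks.test(ss$beta / ss$se, "pnorm")$p.value, 0.01)
})

test_that("GWAS matches single-variant glm and flags monomorphic variants", {
  co <- fix_cohort()
  ss <- run_gwas(co, "prevalent_case", "logistic")
  j <- 5
  fit <- glm(co$pheno$prevalent_case ~ co$dosages[, j], family = binomial)
  expect_equal(ss$beta[j], unname(coef(fit)[2]), tolerance = 1e-5)
  expect_equal(ss$se[j], sqrt(vcov(fit)[2, 2]), tolerance = 1e-3)
  # force a monomorphic column
  co2 <- co
  co2$dosages[, 3] <- 0L
  ss2 <- run_gwas(co2, "prevalent_case", "logistic")
  expect_true(is.na(ss2$beta[3]) && is.na(ss2$se[3]))
  expect_equal(nrow(ss2), ncol(co2$dosages))   # not dropped
})

test_that("single-variant effect estimates cover the truth", {
  # per-allele log-OR 0.3 at one causal variant; 40 replicates
  hits <- 0
  for (r in 1:40) {
    set.seed(700 + r)
    x <- rbinom(8000, 2, 0.3)
    eta <- -2 + 0.3 * x
    y <- rbinom(8000, 1, plogis(eta))
    v <- data.frame(id = "v1", chr = 1, pos = 1, a1 = "A", a2 = "G",
                    freq = 0.3, stringsAsFactors = FALSE)
    pan <- ld_panel("X", list(list(variants = v, R = matrix(1, 1, 1))))
    co <- structure(list(dosages = matrix(x, ncol = 1,
                                          dimnames = list(NULL, "v1")),
                         pheno = data.frame(y = y), panel = pan,
                         ancestry = "X"), class = "cohort")
    ss <- run_gwas(co, "y", "logistic")
    ci <- ss$beta[1] + c(-1.96, 1.96) * ss$se[1]
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 40 * 0.93 - 2)   # >= 93% coverage expectation with slack
})

test_that("sumstats round-trip preserves values and validates p consistency", {
  ss <- fix_sumstats()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(back$beta, ss$beta, tolerance = 1e-12)
  expect_equal(back$se, ss$se, tolerance = 1e-12)
  bad <- ss
  bad$p[1] <- 0.5
  bad$beta[1] <- 3; bad$se[1] <- 0.1
  write_sumstats(bad, path)
  expect_error(read_sumstats(path), "inconsistent")
})

test_that("cohort and LD panel writers round-trip", {
  pan <- fix_panel()
  dir <- withr::local_tempdir()
  write_ld_panel(pan, file.path(dir, "p"))
  back <- read_ld_panel(file.path(dir, "p"))
  expect_equal(back$ancestry, pan$ancestry)
  expect_equal(length(back$blocks), length(pan$blocks))
  expect_equal(back$blocks[[3]]$R, pan$blocks[[3]]$R, tolerance = 1e-12)
  expect_equal(back$blocks[[3]]$variants$freq, pan$blocks[[3]]$variants$freq,
               tolerance = 1e-12)
})
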