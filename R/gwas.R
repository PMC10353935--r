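# Per-variant marginal GWAS on a simulated cohort, vectorised across
# variants: closed form for linear models, batched 2-parameter Newton
# iterations for logistic models. Monomorphic variants are flagged missing
# rather than dropped.

#' Run a marginal GWAS on a cohort
#'
#' One regression per variant of trait on dosage. `model_type = "logistic"`
#' fits per-variant logistic regressions (intercept + dosage) by Newton
#' iteration, vectorised over variants in batches; covariate adjustment, when
#' requested, enters as a fixed offset from a baseline-only logistic fit.
#' `model_type = "linear"` uses the closed-form least-squares solution after
#' residualizing trait (and, with covariates, dosage) on the adjustment set.
#' Effect sizes are per effect allele (the panel's `a1`).
#'
#' @param cohort a `cohort`.
#' @param trait column name in `cohort$pheno` ("prevalent_case" for the
#'   disease trait, "trait2"... for quantitative traits).
#' @param model_type "logistic" or "linear".
#' @param covariates optional character vector of covariate columns.
#' @param batch_size variants per vectorised batch.
#' @return a `sumstats` data.frame: variant_id, chr, pos, effect_allele,
#'   other_allele, eaf, beta, se, p, n, n_cases. Monomorphic variants carry
#'   NA beta/se/p.
#' @export
run_gwas <- function(cohort, trait = "prevalent_case",
                     model_type = c("logistic", "linear"),
                     covariates = NULL, batch_size = 256L) {
  model_type <- match.arg(model_type)
  assert_that(trait %in% names(cohort$pheno), "trait '%s' not present", trait)
  y <- cohort$pheno[[trait]]
  X <- cohort$dosages
  n <- length(y)
  v <- panel_variants(cohort$panel)
  assert_that(all(colnames(X) == v$id), "dosage columns do not match panel")
  if (model_type == "logistic") {
    assert_that(all(y %in% c(0, 1)), "logistic model requires a 0/1 trait")
  }
  M <- ncol(X)
  eaf <- colMeans(X) / 2
  mono <- eaf <= 0 | eaf >= 1
  beta <- se <- rep(NA_real_, M)

  offset <- rep(0, n)
  if (!is.null(covariates)) {
    cdat <- cohort$pheno[, covariates, drop = FALSE]
    mm <- stats::model.matrix(~ ., data = cdat)
    if (model_type == "logistic") {
      base <- stats::glm.fit(mm, y, family = stats::binomial())
      offset <- as.vector(mm %*% base$coefficients)
    } else {
      y <- stats::lm.fit(mm, y)$residuals
    }
  }

  idx_ok <- which(!mono)
  if (model_type == "linear") {
    for (chunk in split(idx_ok, ceiling(seq_along(idx_ok) / batch_size))) {
      xs <- X[, chunk, drop = FALSE]
      if (!is.null(covariates)) xs <- stats::lm.fit(mm, xs)$residuals
      xc <- sweep(xs, 2, colMeans(xs))
      sxx <- colSums(xc^2)
      yc <- y - mean(y)
      b <- colSums(xc * yc) / sxx
      rss <- sum(yc^2) - b^2 * sxx
      dfree <- n - 2 - if (is.null(covariates)) 0 else ncol(mm) - 1
      s2 <- rss / dfree
      beta[chunk] <- b
      se[chunk] <- sqrt(s2 / sxx)
    }
  } else {
    for (chunk in split(idx_ok, ceiling(seq_along(idx_ok) / batch_size))) {
      fit <- logistic_batch(y, X[, chunk, drop = FALSE], offset)
      beta[chunk] <- fit$beta
      se[chunk] <- fit$se
    }
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    variant_id = v$id, chr = v$chr, pos = v$pos,
    effect_allele = v$a1, other_allele = v$a2,
    eaf = eaf, beta = beta, se = se, p = p, n = n,
    n_cases = if (model_type == "logistic") sum(y == 1) else NA_integer_,
    stringsAsFactors = FALSE)
  class(out) <- c("sumstats", class(out))
  out
}

# Vectorised per-variant logistic regression (intercept + slope), Newton
# updates with 2x2 Hessian solves across all variants of the batch at once.
logistic_batch <- function(y, X, offset, max_iter = 25L, tol = 1e-8) {
  m <- ncol(X)
  a <- rep(stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6)), m)
  b <- rep(0, m)
  for (it in seq_len(max_iter)) {
    eta <- offset + rep(a, each = nrow(X)) + sweep(X, 2, b, "*")
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    g1 <- colSums(r)
    g2 <- colSums(X * r)
    h11 <- colSums(w)
    h12 <- colSums(X * w)
    h22 <- colSums(X^2 * w)
    det <- h11 * h22 - h12^2
    det[det < 1e-12] <- NA
    da <- (h22 * g1 - h12 * g2) / det
    db <- (h11 * g2 - h12 * g1) / det
    da[!is.finite(da)] <- 0
    db[!is.finite(db)] <- 0
    # dampen huge steps (quasi-separation)
    sc <- pmax(1, abs(db) / 5)
    a <- a + da / sc
    b <- b + db / sc
    if (max(abs(da), abs(db)) < tol) break
  }
  eta <- offset + rep(a, each = nrow(X)) + sweep(X, 2, b, "*")
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  h11 <- colSums(w)
  h12 <- colSums(X * w)
  h22 <- colSums(X^2 * w)
  det <- h11 * h22 - h12^2
  se <- sqrt(h11 / det)
  se[det <= 0] <- NA
  list(beta = b, se = se)
}

#' Write GWAS summary statistics to TSV
#'
#' Tab-separated with the canonical column order: variant_id, chr, pos,
#' effect_allele, other_allele, eaf, beta, se, p, n, n_cases.
#'
#' @param sumstats a `sumstats` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n", "n_cases")
  data.table::fwrite(sumstats[, cols], ensure_parent(path), sep = "\t", na = "NA")
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' Validates that se > 0 where present and that p is consistent with the
#' normal approximation from beta/se (relative tolerance 1e-6).
#'
#' @param path TSV file written by [write_sumstats()] or compatible.
#' @return a `sumstats` data.frame.
#' @export
read_sumstats <- function(path) {
  ss <- as.data.frame(data.table::fread(path))
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
            "se", "p", "n")
  miss <- setdiff(need, names(ss))
  assert_that(length(miss) == 0, "sumstats missing columns: %s",
              paste(miss, collapse = ", "))
  ok <- !is.na(ss$se)
  assert_that(all(ss$se[ok] > 0), "se must be > 0")
  pchk <- 2 * stats::pnorm(-abs(ss$beta[ok] / ss$se[ok]))
  bad <- abs(pchk - ss$p[ok]) > 1e-6 * pmax(pchk, 1e-300)
  assert_that(!any(bad, na.rm = TRUE), "p values inconsistent with beta/se")
  class(ss) <- c("sumstats", class(ss))
  ss
}
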