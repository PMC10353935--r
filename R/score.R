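# Turning weight sets into per-individual scores: allele matching, dosage x
# weight accumulation, PC residualization and per-ancestry standardization.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Match scoring-file alleles to cohort variants
#'
#' Exact matches keep weight and orientation; swapped alleles keep the weight
#' but mark the dosage complement (2 - dosage); strand-flipped matches
#' (complement bases) are resolved the same way after complementing; and
#' strand-ambiguous variants (A/T or C/G) are dropped. Variants absent from
#' the cohort are dropped. The report counts kept / swapped / flipped /
#' dropped.
#'
#' @param weights a `weight_set`.
#' @param cohort_variants data.frame with columns `id`, `a1`, `a2` (cohort
#'   orientation: dosage counts `a1`).
#' @return list: `aligned` data.frame (id, weight, complement flag),
#'   `report` named counts.
#' @export
match_alleles <- function(weights, cohort_variants) {
  m <- merge(as.data.frame(weights), cohort_variants, by = "id",
             suffixes = c("", ".cohort"))
  ambiguous <- COMPLEMENT[m$effect_allele] == m$other_allele
  ea <- m$effect_allele; oa <- m$other_allele
  exact <- ea == m$a1 & oa == m$a2
  swapped <- ea == m$a2 & oa == m$a1
  flip_ea <- unname(COMPLEMENT[ea]); flip_oa <- unname(COMPLEMENT[oa])
  flipped <- flip_ea == m$a1 & flip_oa == m$a2
  flip_swapped <- flip_ea == m$a2 & flip_oa == m$a1
  keep <- !ambiguous & (exact | swapped | flipped | flip_swapped)
  complement <- (swapped | flip_swapped)[keep]
  aligned <- data.frame(id = m$id[keep], weight = m$weight[keep],
                        complement = complement, stringsAsFactors = FALSE)
  report <- c(kept = sum(keep & (exact | flipped)),
              swapped = sum(keep & complement),
              flipped = sum(keep & (flipped | flip_swapped)),
              dropped_ambiguous = sum(ambiguous),
              dropped_mismatch = sum(!ambiguous & !keep),
              dropped_absent = nrow(weights) - nrow(m))
  assert_that(nrow(aligned) > 0, "no variants matched between weights and cohort")
  list(aligned = aligned, report = report)
}

#' Raw polygenic scores
#'
#' score_i = sum_j dosage_ij * w_j, with the dosage complement (2 - dosage)
#' applied to swap-resolved variants and missing dosages imputed to twice the
#' effect-allele frequency. Accumulation split by chromosome equals a single
#' pass to 1e-10 (linearity), which the test suite checks.
#'
#' @param dosages n x M dosage matrix with variant-id column names.
#' @param aligned data.frame from [match_alleles()] (`id`, `weight`,
#'   `complement`), or a `weight_set` already oriented to the cohort.
#' @param freq optional effect-allele frequencies for mean-imputing missing
#'   dosages (named by variant id).
#' @return numeric vector of raw scores, named by sample.
#' @export
compute_raw_scores <- function(dosages, aligned, freq = NULL) {
  if (inherits(aligned, "weight_set")) {
    aligned <- data.frame(id = aligned$id, weight = aligned$weight,
                          complement = FALSE)
  }
  idx <- match(aligned$id, colnames(dosages))
  assert_that(!anyNA(idx), "aligned variants missing from dosage matrix")
  w <- ifelse(aligned$complement, -aligned$weight, aligned$weight)
  const <- 2 * sum(aligned$weight[aligned$complement])
  D <- dosages[, idx, drop = FALSE]
  if (anyNA(D)) {
    assert_that(!is.null(freq), "missing dosages require freq for imputation")
    f <- freq[aligned$id]
    for (j in which(colSums(is.na(D)) > 0)) {
      D[is.na(D[, j]), j] <- 2 * f[j]
    }
  }
  drop(D %*% w) + const
}

#' Residualize and standardize scores within ancestry groups
#'
#' Within each ancestry group independently, the raw score is residualized on
#' the ten principal components (ordinary least squares with intercept,
#' collinear columns dropped with a warning) and then scaled to mean 0, SD 1.
#' When `constants` from a training cohort are supplied, the training PC
#' coefficients, mean and SD are applied instead of refitting, so validation
#' scores are standardized without leakage.
#'
#' @param raw numeric raw scores.
#' @param pcs matrix/data.frame of 10 principal components.
#' @param ancestry character/factor group labels.
#' @param constants optional list returned by a previous call (field
#'   `constants`).
#' @param min_group minimum samples per group (default 30).
#' @return list: `standardized` numeric vector, `constants` per-group list of
#'   `coef`, `mean`, `sd`.
#' @export
standardize_scores <- function(raw, pcs, ancestry, constants = NULL,
                               min_group = 30L) {
  pcs <- as.matrix(pcs)
  assert_that(ncol(pcs) == 10, "PC matrix must have 10 columns")
  out <- rep(NA_real_, length(raw))
  consts <- list()
  for (g in unique(ancestry)) {
    i <- which(ancestry == g)
    Xg <- cbind(1, pcs[i, , drop = FALSE])
    if (!is.null(constants)) {
      cg <- constants[[g]]
      assert_that(!is.null(cg), "no standardization constants for group %s", g)
      resid <- raw[i] - drop(Xg %*% cg$coef)
      out[i] <- (resid - cg$mean) / cg$sd
      consts[[g]] <- cg
      next
    }
    assert_that(length(i) >= min_group,
                "ancestry group %s has fewer than %d samples", g, min_group)
    qr_ <- qr(Xg)
    if (qr_$rank < ncol(Xg)) {
      warning(sprintf("group %s: dropping %d collinear PC column(s)",
                      g, ncol(Xg) - qr_$rank))
    }
    cf <- qr.coef(qr_, raw[i])
    cf[is.na(cf)] <- 0
    resid <- raw[i] - drop(Xg %*% cf)
    s <- stats::sd(resid)
    assert_that(is.finite(s) && s > 1e-12,
                "group %s: residual score variance is zero", g)
    mu <- mean(resid)
    out[i] <- (resid - mu) / s
    consts[[g]] <- list(coef = cf, mean = mu, sd = s)
  }
  list(standardized = out, constants = consts)
}

#' Score a cohort with a weight set
#'
#' Allele matching, raw accumulation and per-ancestry standardization in one
#' call.
#'
#' @param cohort a `cohort`.
#' @param ws a `weight_set`.
#' @param constants optional training standardization constants.
#' @return list: `raw`, `standardized`, `constants`, `match_report`.
#' @export
score_cohort <- function(cohort, ws, constants = NULL) {
  cv <- panel_variants(cohort$panel)[, c("id", "a1", "a2")]
  ma <- match_alleles(ws, cv)
  raw <- compute_raw_scores(cohort$dosages, ma$aligned)
  st <- standardize_scores(raw, cohort$pheno[, paste0("PC", 1:10)],
                           cohort$pheno$ancestry, constants = constants)
  list(raw = raw, standardized = st$standardized, constants = st$constants,
       match_report = ma$report)
}

#' Write a per-sample score table
#'
#' @param scores list from [score_cohort()].
#' @param cohort the scored `cohort`.
#' @param score_id identifier recorded in the table.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, cohort, score_id, path) {
  data.table::fwrite(data.frame(
    sample_id = cohort$pheno$sample_id,
    raw = scores$raw, standardized = scores$standardized,
    ancestry = cohort$pheno$ancestry, score_id = score_id),
    ensure_parent(path), sep = "\t")
  invisible(path)
}
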